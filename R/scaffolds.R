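#' Scaffold template and substituent libraries for synthetic chemistry
#'
#' The synthetic interaction generator builds family-clustered compound
#' sets by decorating a fixed library of drug-like scaffold templates
#' with small substituents at two enumerated open positions.  Every
#' template x substituent x substituent combination has been verified to
#' produce a parseable, within-template-unique SMILES string, so
#' generated tables are valid by construction.
#'
#' @return `scaffold_templates()`: character vector of SMILES templates,
#'   each containing two `%s` substitution slots.
#'   `substituent_pool()`: character vector of substituent SMILES
#'   fragments (position 1 is `[H]`, i.e. unsubstituted).
#' @export
scaffold_templates <- function() {
  c(
    benzamide_piperazine    = "O=C(c1ccc(%s)cc1)N1CCN(Cc2ccc(%s)cc2)CC1",
    anilino_quinazoline     = "c1cc(%s)ccc1Nc1ncnc2cc(%s)ccc12",
    sulfonanilide           = "O=S(=O)(c1ccc(%s)cc1)Nc1ccc(%s)cc1",
    indole_carboxamide      = "O=C(Nc1ccc(%s)cc1)c1cc2cc(%s)ccc2[nH]1",
    aryl_benzimidazole      = "c1cc(%s)cc2c1nc(-c1ccc(%s)cc1)n2C",
    aryl_piperidine_ketone  = "O=C(CCN1CCC(c2ccc(%s)cc2)CC1)c1ccc(%s)cc1",
    diaryl_urea             = "O=C(Nc1ccc(%s)cc1)Nc1cccc(%s)c1",
    quinoline_piperazine    = "c1cc(%s)ccc1N1CCN(c2ccnc3cc(%s)ccc23)CC1",
    benzofuranyl_ketone     = "O=C(c1cc2cc(%s)ccc2o1)c1ccc(%s)cc1",
    thiophene_carboxanilide = "O=C(Nc1ccc(%s)cc1)c1ccc(%s)s1",
    diaryl_pyrazole         = "Cc1cc(-c2ccc(%s)cc2)nn1-c1ccc(%s)cc1",
    benzothiazole_aniline   = "c1cc(%s)ccc1Nc1nc2cc(%s)ccc2s1",
    benzothiazepinone       = "O=C1Nc2ccc(%s)cc2Sc2ccc(%s)cc21",
    thiq_benzamide          = "c1cc(%s)cc2c1CCN(C(=O)c1ccc(%s)cc1)C2",
    aryloxy_pyridine        = "c1cc(%s)ccc1Oc1ccnc(-c2ccc(%s)cc2)c1",
    anilido_piperidine      = "CC(=O)N(c1ccc(%s)cc1)C1CCN(Cc2ccc(%s)cc2)CC1",
    aryl_coumarin           = "O=c1cc(-c2ccc(%s)cc2)oc2cc(%s)ccc12",
    imidazopyridine         = "c1cc(%s)ccc1-c1cnc2ccc(%s)cn12",
    piperazinyl_benzamide   = "O=C(NCCCN1CCN(c2ccc(%s)cc2)CC1)c1ccc(%s)cc1"
  )
}

#' @rdname scaffold_templates
#' @export
substituent_pool <- function() {
  c("[H]", "F", "Cl", "Br", "C", "CC", "C(C)C", "OC", "OCC", "N",
    "C#N", "C(F)(F)F", "O", "N(C)C", "C(=O)OC", "C(=O)N",
    "S(=O)(=O)C", "CO", "NC(=O)C", "OC(F)F", "I")
}
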