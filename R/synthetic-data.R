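#' Configuration for the synthetic GPCR-ligand interaction generator
#'
#' The generator emulates the structure of a large public GPCR-ligand
#' association database: compounds cluster chemically by target family
#' (each family draws from its own scaffold templates, varied only at
#' two substituent positions), a fraction of compounds are promiscuous
#' (annotated against a second family), records can be exactly
#' duplicated, and some interactions are reported for non-human species.
#' The redundancy artifacts are what the ingestion filters downstream
#' are designed to remove.
#'
#' @param n_families Number of GPCR families (>= 2).
#' @param compounds_per_family Unique human compounds generated per
#'   family.  Limited by the combinatorial capacity
#'   `scaffolds_per_family * substituent_pool_size^2` since compounds are
#'   drawn without replacement.
#' @param scaffolds_per_family Scaffold templates assigned to each
#'   family.  Families receive disjoint templates while the library
#'   (see [scaffold_templates()]) lasts; beyond that templates are
#'   recycled across families.
#' @param substituent_pool_size Number of substituents used from
#'   [substituent_pool()].
#' @param promiscuous_fraction Fraction of compounds additionally
#'   annotated against a second, randomly chosen family.
#' @param duplicate_rate Fraction of records appended again verbatim.
#' @param nonhuman_rate Fraction of records re-reported for a non-human
#'   species (mouse/rat/bovine).
#' @param seed Integer seed; the whole table is deterministic given it.
#' @return A `synthetic_chem_config` list.
#' @export
synthetic_chem_config <- function(n_families = 8,
                                  compounds_per_family = 200,
                                  scaffolds_per_family = 2,
                                  substituent_pool_size = 12,
                                  promiscuous_fraction = 0.05,
                                  duplicate_rate = 0.10,
                                  nonhuman_rate = 0.15,
                                  seed = 1L) {
  n_families <- check_count(n_families, "n_families", min = 2)
  compounds_per_family <- check_count(compounds_per_family,
                                      "compounds_per_family")
  scaffolds_per_family <- check_count(scaffolds_per_family,
                                      "scaffolds_per_family")
  substituent_pool_size <- check_count(substituent_pool_size,
                                       "substituent_pool_size", min = 2)
  if (substituent_pool_size > length(substituent_pool())) {
    config_error("substituent_pool_size exceeds the shipped pool")
  }
  check_fraction(promiscuous_fraction, "promiscuous_fraction")
  check_fraction(duplicate_rate, "duplicate_rate")
  check_fraction(nonhuman_rate, "nonhuman_rate")
  capacity <- scaffolds_per_family * substituent_pool_size^2
  if (compounds_per_family > capacity) {
    config_error(sprintf(
      "compounds_per_family (%d) exceeds combinatorial capacity (%d); raise scaffolds_per_family or substituent_pool_size",
      compounds_per_family, capacity))
  }
  structure(list(n_families = n_families,
                 compounds_per_family = compounds_per_family,
                 scaffolds_per_family = scaffolds_per_family,
                 substituent_pool_size = substituent_pool_size,
                 promiscuous_fraction = promiscuous_fraction,
                 duplicate_rate = duplicate_rate,
                 nonhuman_rate = nonhuman_rate,
                 seed = as.integer(seed)),
            class = "synthetic_chem_config")
}

#' Generate a synthetic GPCR-ligand interaction table
#'
#' Builds one record per compound-family annotation with columns
#' `compound_id`, `smiles`, `receptor`, `species`, `family`.  Compounds
#' within a family are unique decorations of the family's scaffold
#' templates, so every SMILES parses by construction and within-family
#' chemical similarity exceeds between-family similarity.
#'
#' @param config A [synthetic_chem_config()].
#' @return A data.frame of interaction records.
#' @export
generate_interaction_table <- function(config) {
  stopifnot(inherits(config, "synthetic_chem_config"))
  templates <- scaffold_templates()
  subs <- substituent_pool()[seq_len(config$substituent_pool_size)]
  nf <- config$n_families
  spf <- config$scaffolds_per_family
  if (nf * spf > length(templates)) {
    warning("scaffold library smaller than n_families * scaffolds_per_family; ",
            "templates are recycled across families", call. = FALSE)
  }
  families <- sprintf("FAM%02d", seq_len(nf))

  with_seed(config$seed, {
    recs <- vector("list", nf)
    cid0 <- 0L
    for (f in seq_len(nf)) {
      tmpl_idx <- ((f - 1L) * spf + seq_len(spf) - 1L) %% length(templates) + 1L
      combos <- expand.grid(s = tmpl_idx,
                            a = seq_along(subs), b = seq_along(subs))
      pick <- combos[sample.int(nrow(combos), config$compounds_per_family), ]
      smiles <- sprintf(templates[pick$s], subs[pick$a], subs[pick$b])
      ids <- sprintf("CPD%06d", cid0 + seq_along(smiles))
      cid0 <- cid0 + length(smiles)
      receptors <- sprintf("%s_R%d", families[f],
                           sample.int(4L, length(smiles), replace = TRUE))
      recs[[f]] <- data.frame(compound_id = ids, smiles = smiles,
                              receptor = receptors, species = "human",
                              family = families[f],
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, recs)

    # promiscuous compounds: same structure annotated against a second family
    n_prom <- floor(config$promiscuous_fraction * nrow(tab))
    if (n_prom > 0) {
      idx <- sample.int(nrow(tab), n_prom)
      second <- vapply(tab$family[idx], function(f) {
        sample(setdiff(families, f), 1L)
      }, character(1))
      extra <- tab[idx, ]
      extra$family <- second
      extra$receptor <- sprintf("%s_R%d", second,
                                sample.int(4L, n_prom, replace = TRUE))
      tab <- rbind(tab, extra)
    }

    # redundancy artifacts removed by the ingestion pipeline
    n_dup <- round(config$duplicate_rate * nrow(tab))
    if (n_dup > 0) tab <- rbind(tab, tab[sample.int(nrow(tab), n_dup), ])
    n_nh <- round(config$nonhuman_rate * nrow(tab))
    if (n_nh > 0) {
      nh <- tab[sample.int(nrow(tab), n_nh), ]
      nh$species <- sample(c("mouse", "rat", "bovine"), n_nh, replace = TRUE)
      tab <- rbind(tab, nh)
    }
    tab <- tab[sample.int(nrow(tab)), ]
    rownames(tab) <- NULL
    tab
  })
}

#' Configuration for simulated NanoBRET plates and saturation series
#'
#' Emissions are decomposed as a fixed donor channel (10^6 counts) with
#' the acceptor channel carrying the BRET signal plus Gaussian noise, so
#' acceptor/donor recovers the intended BRET ratio.  For a bound
#' construct-tracer pair, tracer-alone wells have expected BRET
#' `true_fold_response * background_bret` while competitor-blocked wells
#' fall back to `background_bret`; unbound pairs sit at background in
#' both conditions.
#'
#' @param true_fold_response Expected fold response of a bound pair.
#' @param background_bret Nonspecific BRET ratio common to all wells.
#' @param noise_sd Gaussian noise SD on the BRET-ratio scale.  The
#'   default 0.007 reproduces the empirical plate behaviour in which a
#'   1.5-fold response corresponds to roughly a 7-fold signal over noise.
#' @param n_replicates Wells per condition (triplicates by default,
#'   matching signal-to-noise estimation practice).
#' @param bmax Saturation-binding plateau (BRET units).
#' @param ec50 Half-saturating tracer concentration (nM).
#' @param concentrations Tracer concentrations in nM, strictly positive
#'   and sorted ascending.  Default: two-fold dilutions from 1000 nM.
#' @param seed Integer seed.
#' @return A `synthetic_bret_config` list.
#' @export
synthetic_bret_config <- function(true_fold_response = 2.0,
                                  background_bret = 0.1,
                                  noise_sd = 0.007,
                                  n_replicates = 3,
                                  bmax = 0.2,
                                  ec50 = 50,
                                  concentrations = 1000 / 2^(7:0),
                                  seed = 1L) {
  if (true_fold_response <= 0) config_error("true_fold_response must be > 0")
  if (background_bret <= 0) config_error("background_bret must be > 0")
  if (noise_sd < 0) config_error("noise_sd must be >= 0")
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (bmax <= 0) config_error("bmax must be > 0")
  if (ec50 <= 0) config_error("ec50 must be > 0")
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    config_error("concentrations must be strictly positive and sorted ascending")
  }
  structure(list(true_fold_response = true_fold_response,
                 background_bret = background_bret,
                 noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 bmax = bmax, ec50 = ec50,
                 concentrations = as.numeric(concentrations),
                 seed = as.integer(seed)),
            class = "synthetic_bret_config")
}

DONOR_COUNTS <- 1e6

make_wells <- function(construct, tracer, concentration, condition,
                       expected_bret, noise_sd) {
  n <- length(expected_bret)
  donor <- rep(DONOR_COUNTS, n)
  acceptor <- expected_bret * donor + stats::rnorm(n, 0, noise_sd * DONOR_COUNTS)
  acceptor <- pmax(acceptor, 1)
  data.frame(plate = ceiling(seq_len(n) / 96),
             well = sprintf("W%04d", seq_len(n)),
             construct = construct, tracer = tracer,
             concentration_nM = concentration, condition = condition,
             donor_em = donor, acceptor_em = acceptor,
             stringsAsFactors = FALSE)
}

#' Simulate a NanoBRET competitive-screen plate table
#'
#' @param config A [synthetic_bret_config()].
#' @param truth Data.frame with columns `construct`, `tracer` and either
#'   a logical `bound` column or a numeric `fold_response` column giving
#'   the per-pair expected fold (unbound pairs have fold 1).
#' @return A long-format plate table with columns `plate`, `well`,
#'   `construct`, `tracer`, `concentration_nM`, `condition`, `donor_em`,
#'   `acceptor_em`.
#' @export
generate_bret_plate <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_bret_config"))
  require_columns(truth, c("construct", "tracer"), "truth map")
  if (!is.null(truth$fold_response)) {
    fold <- as.numeric(truth$fold_response)
  } else if (!is.null(truth$bound)) {
    fold <- ifelse(truth$bound, config$true_fold_response, 1)
  } else {
    schema_error("truth map needs a 'bound' or 'fold_response' column")
  }

  with_seed(config$seed, {
    out <- vector("list", nrow(truth) * length(config$concentrations) * 2L)
    k <- 0L
    for (i in seq_len(nrow(truth))) {
      for (conc in config$concentrations) {
        bt <- rep(config$background_bret * fold[i], config$n_replicates)
        bc <- rep(config$background_bret, config$n_replicates)
        k <- k + 1L
        out[[k]] <- make_wells(truth$construct[i], truth$tracer[i], conc,
                               "tracer_alone", bt, config$noise_sd)
        k <- k + 1L
        out[[k]] <- make_wells(truth$construct[i], truth$tracer[i], conc,
                               "tracer_plus_competitor", bc, config$noise_sd)
      }
    }
    tab <- do.call(rbind, out)
    tab$well <- sprintf("W%05d", seq_len(nrow(tab)))
    tab$plate <- ceiling(seq_len(nrow(tab)) / 96)
    tab
  })
}

#' Simulate a saturation-binding dose-response series
#'
#' Tracer-alone wells follow `background + bmax * c / (ec50 + c)`;
#' paired competitor wells carry background only, so background
#' correction by subtraction recovers the one-site hyperbola.
#'
#' @param config A [synthetic_bret_config()] with >= 4 concentrations.
#' @param construct,tracer Identifiers stamped on the wells.
#' @return Plate-format data.frame as in [generate_bret_plate()].
#' @export
generate_saturation_series <- function(config, construct = "HIBIT_GPCR",
                                       tracer = "TRACER") {
  stopifnot(inherits(config, "synthetic_bret_config"))
  if (length(config$concentrations) < 4) {
    config_error("saturation series needs >= 4 concentrations")
  }
  with_seed(config$seed, {
    out <- list()
    for (conc in config$concentrations) {
      specific <- config$bmax * conc / (config$ec50 + conc)
      bt <- rep(config$background_bret + specific, config$n_replicates)
      bc <- rep(config$background_bret, config$n_replicates)
      out[[length(out) + 1L]] <- make_wells(construct, tracer, conc,
                                            "tracer_alone", bt,
                                            config$noise_sd)
      out[[length(out) + 1L]] <- make_wells(construct, tracer, conc,
                                            "tracer_plus_competitor", bc,
                                            config$noise_sd)
    }
    tab <- do.call(rbind, out)
    tab$well <- sprintf("W%05d", seq_len(nrow(tab)))
    tab$plate <- ceiling(seq_len(nrow(tab)) / 96)
    tab
  })
}
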