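# Shared fixtures, generated once per test run.  Fingerprinting crosses
# into the Python backend, so expensive fixtures are memoised here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# clean 4-family table (no redundancy artifacts) plus fingerprints
chem_fixture <- function() {
  memo("chem4", {
    cfg <- synthetic_chem_config(n_families = 4, compounds_per_family = 60,
                                 promiscuous_fraction = 0, duplicate_rate = 0,
                                 nonhuman_rate = 0, seed = 101)
    tab <- generate_interaction_table(cfg)
    fp <- fingerprint_matrix(tab$smiles, tab$compound_id)
    list(config = cfg, table = tab, fp = fp)
  })
}

# one small trained model shared across test files
trained_fixture <- function() {
  memo("trained4", {
    fx <- chem_fixture()
    tab <- fx$table
    sp <- stratified_split(tab, 0.7, seed = 5)
    xtr <- fx$fp[match(sp$training$compound_id, tab$compound_id), ]
    xte <- fx$fp[match(sp$test$compound_id, tab$compound_id), ]
    mask <- fit_nzv_mask(xtr)
    model <- train_family_classifier(apply_mask(xtr, mask),
                                     sp$training$family,
                                     cv = cv_config(3, 1), num_trees = 100,
                                     seed = 11, feature_mask = mask)
    list(model = model, mask = mask,
         xtr = apply_mask(xtr, mask), ytr = sp$training$family,
         xte = apply_mask(xte, mask), yte = sp$test$family)
  })
}

# independent all-pairs Tanimoto, deliberately naive (oracle)
naive_tanimoto <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# independent one-vs-rest recount from raw prediction lists (oracle)
naive_family_metrics <- function(true, pred, fam) {
  tp <- sum(true == fam & pred == fam)
  fn <- sum(true == fam & pred != fam)
  fp <- sum(true != fam & pred == fam)
  tn <- sum(true != fam & pred != fam)
  c(accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}
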