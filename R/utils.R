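`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a locally-seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("gpcrtracer_config_error", "error")))
}

schema_error <- function(msg) {
  stop(errorCondition(msg, class = c("gpcrtracer_schema_error", "error")))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    config_error(sprintf("'%s' must be a single value in [0, 1]", name))
  }
  x
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x)) {
    config_error(sprintf("'%s' must be an integer >= %d", name, min))
  }
  as.integer(x)
}

require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    schema_error(sprintf("%s is missing required column(s): %s", what,
                         paste(missing, collapse = ", ")))
  }
  invisible(df)
}
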