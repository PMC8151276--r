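#' Convert classifier probabilities to percent-scale profiles
#'
#' Class probabilities are rescaled to 0-100% for readability; each
#' compound's profile sums to 100 within 1e-6.
#'
#' @param probs Matrix from [predict_family_probs()] (rows sum to 1) or
#'   a single named probability vector.
#' @return Matrix of percent-scale profiles (class
#'   `probability_profiles`).
#' @export
probability_profiles <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, names(probs)))
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    schema_error("probability rows must sum to 1")
  }
  structure(probs * 100, class = c("probability_profiles", "matrix"))
}

#' Threshold a probability profile into predicted family interactions
#'
#' Families whose classification probability is at or above the
#' threshold are flagged as predicted positive interactions.  The
#' comparison is inclusive (>=); a profile entirely below threshold
#' yields an empty set rather than being forced to its top class.
#'
#' @param profile Named numeric vector of percent-scale probabilities
#'   (summing to 100), e.g. one row of [probability_profiles()].
#' @param threshold Percent threshold, default 4.
#' @return List with `positive_families` (character) and `threshold`.
#' @export
predict_profile <- function(profile, threshold = 4) {
  if (threshold < 0) config_error("threshold must be >= 0")
  if (is.null(names(profile))) schema_error("profile must be named by family")
  if (abs(sum(profile) - 100) > 1e-6) {
    schema_error("percent profile must sum to 100")
  }
  list(positive_families = names(profile)[profile >= threshold],
       threshold = threshold)
}

#' Binary scaffold x family call matrix from probability profiles
#'
#' @param profiles A `probability_profiles` matrix (percent scale), or a
#'   list of named percent vectors sharing one family set.
#' @param families Ordered family labels; must match the profiles'
#'   family set exactly.
#' @param threshold Percent threshold (inclusive), default 4.
#' @return Binary 0/1 matrix, one row per profile, one column per
#'   family.
#' @export
profile_matrix <- function(profiles, families, threshold = 4) {
  if (threshold < 0) config_error("threshold must be >= 0")
  if (is.list(profiles) && is.null(dim(profiles))) {
    profiles <- do.call(rbind, profiles)
  }
  if (length(profiles) == 0 || nrow(profiles) == 0) {
    return(matrix(0L, nrow = 0, ncol = length(families),
                  dimnames = list(NULL, families)))
  }
  if (is.null(colnames(profiles)) ||
      !setequal(colnames(profiles), families)) {
    schema_error("profiles' family set does not match 'families'")
  }
  m <- (unclass(profiles)[, families, drop = FALSE] >= threshold) * 1L
  m
}
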