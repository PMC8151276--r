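#' Locate the Python interpreter used by the molecule/model backend
#'
#' Molecule parsing, fingerprinting (RDKit) and random-forest training
#' (scikit-learn) run in a bundled Python helper.  The interpreter is
#' resolved, in order, from `options(gpcrtracer.python=)`, the
#' `GPCRTRACER_PYTHON` environment variable, and `python` on the PATH.
#'
#' @return Path to the interpreter.
#' @export
find_python <- function() {
  cand <- getOption("gpcrtracer.python", "")
  if (!nzchar(cand)) cand <- Sys.getenv("GPCRTRACER_PYTHON", "")
  if (!nzchar(cand)) cand <- Sys.which("python")
  if (!nzchar(cand)) cand <- Sys.which("python3")
  if (!nzchar(cand)) {
    stop("No python interpreter found; set options(gpcrtracer.python=)",
         call. = FALSE)
  }
  unname(cand)
}

py_helper <- function(name) {
  path <- system.file("python", name, package = "gpcrtracer", mustWork = TRUE)
  path
}

run_py <- function(script, args) {
  out <- suppressWarnings(system2(find_python(), c(shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("python backend failed (", basename(script), "):\n",
         paste(out, collapse = "\n"), call. = FALSE)
  }
  invisible(out)
}
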