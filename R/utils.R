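#' @keywords internal
"_PACKAGE"

.metquant_cache <- new.env(parent = emptyenv())

# Internal assertion helpers --------------------------------------------------

stop_mq <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mq(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_mq(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  invisible(x)
}

assert_fraction <- function(x, name, upper = 1) {
  assert_scalar_num(x, name)
  if (x < 0 || x >= upper) {
    stop_mq(sprintf("`%s` must lie in [0, %g) (got %g)", name, upper, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_mq(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "metquant")
  if (!nzchar(path)) stop_mq(sprintf("packaged file '%s' not found", file))
  path
}

read_pkg_csv <- function(file) {
  utils::read.csv(extdata_path(file), stringsAsFactors = FALSE)
}
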