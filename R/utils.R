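# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#: valid strain and medium levels used throughout the package
ss_strains <- function() c("WT", "sdh1", "sdh2", "jlp1")
ss_media <- function() c("AS", "ISE")
ss_roles <- function() c("experimental", "negative_control", "untreated_reference", "blank")

ss_stop <- function(...) stop(..., call. = FALSE)

ss_check_number <- function(x, name, lower = -Inf, upper = Inf,
                            allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L ||
      (!allow_na && (is.na(x) || x < lower || x > upper))) {
    ss_stop(sprintf("'%s' must be a single number in [%g, %g]",
                    name, lower, upper))
  }
  invisible(x)
}

# Run `code` under a fixed seed, restoring the caller's RNG state afterwards.
# All stochastic generator functions take an explicit seed and route here, so
# nothing in the package mutates global random state.
ss_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, force(code))
}

#' Significance stars
#'
#' Conventional star rendering of (adjusted) p-values: `*` < 0.05,
#' `**` < 0.01, `***` < 0.001, otherwise `ns`.
#'
#' @param p numeric p-values.
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- character(length(p))
  out[] <- "ns"
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
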