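# broom-style tidiers for the fitted/summary objects.

#' Tidy a codon-meaning summary
#'
#' @param x A `codon_meaning` from [infer_codon_meaning()].
#' @param ... Unused.
#' @return Tibble `aa`, `count`, `freq`, one row per modal amino acid.
#' @export
tidy.codon_meaning <- function(x, ...) {
  if (x$n_sites == 0) {
    return(tibble(aa = character(0), count = integer(0), freq = double(0)))
  }
  logo_counts(x)
}

#' @rdname tidy.codon_meaning
#' @return `glance()`: one-row tibble with `codon`, `n_sites`, `top_aa`,
#'   `top_fraction`, `threshold`, `insufficient_evidence`.
#' @export
glance.codon_meaning <- function(x, ...) {
  tibble(codon = x$codon, n_sites = x$n_sites, top_aa = x$top_aa,
         top_fraction = x$top_fraction, threshold = x$threshold,
         insufficient_evidence = x$insufficient_evidence)
}

#' Tidy a depletion test
#'
#' @param x A `depletion_test` from [depletion_test()].
#' @param ... Unused.
#' @return One-row tibble: `ratio`, `ci_lower`, `ci_upper`, `verdict`,
#'   `n_target`.
#' @export
tidy.depletion_test <- function(x, ...) {
  tibble(ratio = x$ratio, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         verdict = x$verdict, n_target = x$n_target)
}

#' @rdname tidy.depletion_test
#' @export
glance.depletion_test <- function(x, ...) {
  tibble(ratio = x$ratio, verdict = x$verdict, n_target = x$n_target,
         n_boot = x$n_boot, conf = x$conf,
         tail_fraction = x$tail_fraction)
}

#' Tidy a codon scan
#'
#' @param x A `codon_scan` from [scan_all_codons()].
#' @param ... Unused.
#' @return The per-codon call table as a plain tibble.
#' @export
tidy.codon_scan <- function(x, ...) {
  out <- x
  attr(out, "summaries") <- NULL
  attr(out, "hits") <- NULL
  class(out) <- setdiff(class(out), "codon_scan")
  as_tibble(out)
}

#' Tidy an identity-element report
#'
#' @param x An `identity_element_report` from [check_identity_elements()].
#' @param ... Unused.
#' @return The per-element table as a plain tibble.
#' @export
tidy.identity_element_report <- function(x, ...) {
  out <- x
  attr(out, "overall_pass") <- NULL
  class(out) <- setdiff(class(out), "identity_element_report")
  as_tibble(out)
}

#' @rdname tidy.identity_element_report
#' @export
glance.identity_element_report <- function(x, ...) {
  tibble(overall_pass = attr(x, "overall_pass"),
         n_pass = sum(x$pass, na.rm = TRUE),
         n_fail = sum(!x$pass, na.rm = TRUE),
         n_unevaluable = sum(!x$evaluable))
}
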