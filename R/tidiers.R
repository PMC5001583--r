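#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Welch comparison of fold changes
#'
#' @param x A [fold_change_by_location()] result.
#' @param ... Unused.
#' @return One-row tibble with the group means, t statistic,
#'   Welch-Satterthwaite df and two-sided p-value.
#' @method tidy welch_comparison
#' @export
tidy.welch_comparison <- function(x, ...) {
  tibble(estimate_tss = x$groups$mean[x$groups$group == "tss"],
         estimate_distal = x$groups$mean[x$groups$group == "distal"],
         statistic = x$statistic, df = x$df, p.value = x$p_value,
         method = "Welch two-sample t-test")
}

#' @rdname tidy.welch_comparison
#' @method glance welch_comparison
#' @export
glance.welch_comparison <- function(x, ...) tidy(x, ...)

#' Tidy a repeat-age profile
#'
#' @param x A [summit_repeat_ages()] result.
#' @param ... Unused.
#' @return The per-HMR age samples as a tibble.
#' @method tidy repeat_age_profile
#' @export
tidy.repeat_age_profile <- function(x, ...) x$samples

#' @rdname tidy.repeat_age_profile
#' @return For `glance()`: one row per compared group pair with the
#'   Mann-Whitney U statistic and p-value (empty tibble when no comparison
#'   was requested).
#' @method glance repeat_age_profile
#' @export
glance.repeat_age_profile <- function(x, ...) {
  x$test %||% tibble(group1 = character(), group2 = character(),
                     n1 = integer(), n2 = integer(), statistic = numeric(),
                     p_value = numeric(), method = character())
}

#' Tidy a multi-way overlap summary
#'
#' @param x A [multiway_overlap_summary()] result.
#' @param ... Unused.
#' @return The membership-pattern counts.
#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) x$patterns

#' @rdname tidy.overlap_summary
#' @method glance overlap_summary
#' @export
glance.overlap_summary <- function(x, ...) {
  tibble(n_targets = x$n_targets, n_any = x$n_any,
         percent_any = x$percent_any)
}

#' Tidy a pipeline run report
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return For `tidy()`: per-label HMR counts; for `glance()`: a one-row
#'   tibble of the headline run statistics.
#' @method tidy hmr_run_report
#' @export
tidy.hmr_run_report <- function(x, ...) {
  tibble(label = names(x$report$n_by_label),
         n = unlist(x$report$n_by_label))
}

#' @rdname tidy.hmr_run_report
#' @method glance hmr_run_report
#' @export
glance.hmr_run_report <- function(x, ...) {
  r <- x$report
  tibble(n_hmrs_a = r$n_hmrs$A, n_hmrs_b = r$n_hmrs$B, n_union = r$n_union,
         fraction_shared = r$fraction_shared,
         fraction_a_recapitulated_in_b = r$fraction_a_recapitulated_in_b,
         fraction_b_recapitulated_in_a = r$fraction_b_recapitulated_in_a,
         bisulfite_conversion = r$bisulfite_conversion)
}
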