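#' Empirical cumulative distribution of allele frequencies
#'
#' Thin wrapper around [stats::ecdf()]: the returned function reports the
#' fraction of values less than or equal to a threshold (right-continuous).
#'
#' @param values Numeric vector (nonempty).
#' @return An `ecdf` function.
#' @examples
#' af_cdf(c(0.1, 0.4, 0.6))(0.5) # 2/3
#' @export
af_cdf <- function(values) {
  if (length(values) == 0 || all(is.na(values))) {
    abort("`values` must contain at least one non-missing value.")
  }
  stats::ecdf(values[!is.na(values)])
}

#' Tabulate a CDF at chosen thresholds
#'
#' @param values Numeric vector.
#' @param thresholds Query thresholds (default: a fine grid on `[0, 1]`).
#' @return Tibble with `threshold` and `cum_fraction`.
#' @export
cdf_table <- function(values, thresholds = seq(0, 1, by = 0.01)) {
  f <- af_cdf(values)
  tibble(threshold = thresholds, cum_fraction = f(thresholds))
}

#' Count reference sites carrying the minor allele
#'
#' How many sites of an allele vector carry the allele whose population
#' frequency is strictly below 0.5; ties at exactly 0.5 are not counted.
#' Applied to the reference's carried-allele spectrum this is the headline
#' "reference carries the minor allele" count.
#'
#' @param carried_af Carried-allele frequencies, e.g. from
#'   [reference_allele_spectrum()].
#' @return Integer count.
#' @examples
#' minor_allele_site_count(c(0.3, 0.5, 0.7)) # 1
#' @export
minor_allele_site_count <- function(carried_af) {
  sum(carried_af < 0.5, na.rm = TRUE)
}

#' Fraction of calls whose called allele is the major allele
#'
#' For a per-call table, the fraction of homozygous calls whose
#' called-allele frequency exceeds 0.5, and the same for heterozygous
#' calls. Against a type-specimen reference both fractions are substantial
#' (the "variant" is often the population's major allele); against a
#' consensus both are exactly zero by construction.
#'
#' @param calls Per-call tibble with `zygosity` and `called_af` (e.g.
#'   `call_variants(...)$calls`), or a `variant_calls` object.
#' @return Tibble with `zygosity`, `n_calls`, `n_af_above_half`,
#'   `frac_af_above_half`.
#' @export
zygosity_af_fractions <- function(calls) {
  if (inherits(calls, "variant_calls")) {
    if (is.null(calls$calls)) {
      abort("This `variant_calls` was built with keep_calls = FALSE.")
    }
    calls <- calls$calls
  }
  calls |>
    group_by(.data$zygosity) |>
    summarise(
      n_calls = n(),
      n_af_above_half = sum(.data$called_af > 0.5),
      frac_af_above_half = mean(.data$called_af > 0.5),
      .groups = "drop"
    )
}

scope_order <- function(scopes) {
  lead <- c("reference", "ALL", "superpopulation", "population-matched",
            "population-mean")
  c(intersect(lead, scopes), setdiff(scopes, lead))
}

#' Summarise per-genome homozygous-variant counts across reference choices
#'
#' One row per reference scope: sample count, mean, median, standard
#' deviation, and the mode of a histogram with the given bin width (the
#' headline statistic when distributions are read off their modal peaks).
#' Scopes are ordered reference, global consensus, then population scopes.
#'
#' @param summaries Per-sample summary tibble(s) with `sample`, `scope`,
#'   `n_hom` -- e.g. `dplyr::bind_rows` of `call_variants(...)$summary`
#'   across scopes, or a list of `variant_calls`.
#' @param binwidth Histogram bin width for the mode; default
#'   `max(1, diff(range(n_hom)) / 30)`.
#' @return Tibble with `scope`, `n_samples`, `mean_hom`, `median_hom`,
#'   `sd_hom`, `mode_hom`.
#' @export
summarize_hom_distribution <- function(summaries, binwidth = NULL) {
  if (inherits(summaries, "variant_calls")) summaries <- list(summaries)
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- purrr::list_rbind(purrr::map(summaries, function(x) {
      if (inherits(x, "variant_calls")) x$summary else as_tibble(x)
    }))
  }
  counts_by_scope <- split(summaries$n_hom, summaries$scope)
  if (any(lengths(counts_by_scope) < 2L)) {
    abort("Each scope needs at least two samples to summarise a distribution.")
  }
  hist_mode <- function(x, bw) {
    breaks <- seq(min(x) - bw / 2, max(x) + bw, by = bw)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  out <- summaries |>
    group_by(.data$scope) |>
    summarise(
      n_samples = n(),
      mean_hom = mean(.data$n_hom),
      median_hom = stats::median(.data$n_hom),
      sd_hom = stats::sd(.data$n_hom),
      mode_hom = {
        bw <- binwidth %||% max(1, diff(range(.data$n_hom)) / 30)
        hist_mode(.data$n_hom, bw)
      },
      .groups = "drop"
    )
  out[match(scope_order(out$scope), out$scope), ]
}

#' Cumulative AF curves for called variants, split by zygosity
#'
#' The classic reference-bias picture: against a type-specimen reference a
#' large share of hom (and a smaller share of het) calls sit above AF 0.5;
#' against a consensus every curve saturates at 0.5.
#'
#' @param calls Per-call tibble (or `variant_calls`) with `zygosity`,
#'   `called_af`, and optionally `scope`.
#' @return A ggplot.
#' @export
plot_af_cdf <- function(calls) {
  if (inherits(calls, "variant_calls")) calls <- calls$calls
  p <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$called_af,
                                           colour = .data$zygosity)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "population AF of called allele",
                  y = "cumulative fraction of calls", colour = NULL) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::theme_minimal()
  if ("scope" %in% names(calls) && length(unique(calls$scope)) > 1) {
    p <- p + ggplot2::facet_wrap(~scope)
  }
  p
}

#' Distribution of per-genome homozygous-variant counts by reference scope
#'
#' @param summaries Combined per-sample summary tibble with `scope` and
#'   `n_hom` (or a list of `variant_calls`).
#' @return A ggplot (density per scope).
#' @export
plot_hom_distribution <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- purrr::list_rbind(purrr::map(summaries, function(x) {
      if (inherits(x, "variant_calls")) x$summary else as_tibble(x)
    }))
  }
  summaries$scope <- factor(summaries$scope,
                            levels = scope_order(unique(summaries$scope)))
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$n_hom,
                                          colour = .data$scope)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "homozygous variant calls per genome", y = "density",
                  colour = "reference") +
    ggplot2::theme_minimal()
}
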