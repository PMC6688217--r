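#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a consensus reference into its switch table
#'
#' @param x A `consensus_ref`.
#' @param ... Unused.
#' @return The switch table tibble (one row per site).
#' @method tidy consensus_ref
#' @export
tidy.consensus_ref <- function(x, ...) {
  x$switch_table
}

#' One-row summary of a consensus reference
#'
#' @param x A `consensus_ref`.
#' @param ... Unused.
#' @return Tibble with `scope`, `n_sites`, `n_swapped`, `prop_swapped`,
#'   `min_carried_af` (frequency of the least-common allele the consensus
#'   carries; >= 0.5 by construction for a true consensus scope).
#' @method glance consensus_ref
#' @export
glance.consensus_ref <- function(x, ...) {
  st <- x$switch_table
  carried <- ifelse(st$swapped, st$af_used, 1 - st$af_used)
  tibble(
    scope = x$scope,
    n_sites = nrow(st),
    n_swapped = sum(st$swapped),
    prop_swapped = mean(st$swapped),
    min_carried_af = min(carried)
  )
}

#' Tidy variant calls into the per-sample summary
#'
#' @param x A `variant_calls`.
#' @param ... Unused.
#' @return Tibble: `sample`, `scope`, `n_hom`, `n_het`.
#' @method tidy variant_calls
#' @export
tidy.variant_calls <- function(x, ...) {
  x$summary
}

#' One-row summary of a set of variant calls
#'
#' @param x A `variant_calls`.
#' @param ... Unused.
#' @return Tibble with `scope`, `n_samples`, `mean_hom`, `mean_het`, and
#'   `max_called_af` (NA when per-call records were not kept).
#' @method glance variant_calls
#' @export
glance.variant_calls <- function(x, ...) {
  tibble(
    scope = x$scope,
    n_samples = nrow(x$summary),
    mean_hom = mean(x$summary$n_hom),
    mean_het = mean(x$summary$n_het),
    max_called_af = if (is.null(x$calls)) NA_real_ else max(x$calls$called_af)
  )
}

#' Tidy an `snv_cohort` into its site table
#'
#' @param x An `snv_cohort`.
#' @param ... Unused.
#' @return The site tibble.
#' @method tidy snv_cohort
#' @export
tidy.snv_cohort <- function(x, ...) {
  x$sites
}

#' One-row summary of an `snv_cohort`
#'
#' @param x An `snv_cohort`.
#' @param ... Unused.
#' @return Tibble with site/sample/population counts and mean ALT AF.
#' @method glance snv_cohort
#' @export
glance.snv_cohort <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_samples = ncol(x$genotypes),
    n_populations = if (is.null(x$samples)) {
      NA_integer_
    } else {
      dplyr::n_distinct(x$samples$population)
    },
    mean_af = mean(x$sites$af_alt)
  )
}
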