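# TD50 label engineering: per-experiment dose-rate observations are turned
# into a single continuous training target per molecule.
#
# TD50 (mg/kg body weight/day) is the dose-rate estimated to halve the
# probability of remaining tumor-free; under the proportional-hazards dose
# model lambda(t, d) = (1 + beta * d) * lambda0(t) it equals log(2) / beta.
# Training targets are log-reciprocal aggregated TD50s: higher = more potent.

#' TD50 from a proportional-hazards dose coefficient
#'
#' @param beta positive hazard coefficient (per mg/kg/day). `beta = 0` means
#'   no dose-tumor relationship, so no finite TD50 exists.
#' @return TD50 in mg/kg/day: `log(2) / beta`.
#' @export
td50_from_beta <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L)
  if (!is.finite(beta) || beta <= 0) {
    .condition_stop("carcipred_no_finite_td50",
                    "beta <= 0: no dose-tumor relationship, TD50 undefined")
  }
  log(2) / beta
}

#' Aggregate multi-experiment TD50 observations
#'
#' Harmonic mean over the experiments with a finite TD50. The harmonic mean
#' biases the aggregate toward low values, i.e. toward the experiments that
#' did demonstrate carcinogenicity; experiments with no tumor response
#' (`NA` TD50) do not enter the mean at all. A molecule is non-carcinogenic
#' only if no experiment produced a finite TD50.
#'
#' @param td50 numeric vector of per-experiment TD50s (mg/kg/day); `NA`
#'   encodes a non-carcinogenic experiment.
#' @return aggregated TD50, or `NA` if all experiments were negative.
#' @export
aggregate_td50 <- function(td50) {
  if (length(td50) == 0L) stop("no potency records to aggregate")
  if (all(is.na(td50))) return(NA_real_)
  stopifnot(is.numeric(td50))
  fin <- td50[!is.na(td50)]
  if (any(fin <= 0)) stop("TD50 values must be positive")
  if (length(fin) == 0L) return(NA_real_)
  length(fin) / sum(1 / fin)
}

#' Log-reciprocal potency label
#'
#' `y = log10(1 / TD50)` for carcinogenic molecules; non-carcinogenic
#' molecules receive a fixed sentinel value (default -1.62, the cluster at
#' which no-tumor-growth experiments sit on the training scale).
#'
#' @param td50_agg aggregated TD50 (`NA` = non-carcinogenic).
#' @param sentinel sentinel log-potency for non-carcinogenic molecules.
#' @param base logarithm base (default 10).
#' @return list with `y` (finite numeric) and `is_sentinel` (logical).
#' @export
to_log_potency <- function(td50_agg, sentinel = -1.62, base = 10) {
  stopifnot(length(td50_agg) == 1L)
  if (is.na(td50_agg)) {
    return(list(y = sentinel, is_sentinel = TRUE))
  }
  stopifnot(td50_agg > 0)
  list(y = log(1 / td50_agg, base = base), is_sentinel = FALSE)
}

#' Binarize continuous potency labels
#'
#' Positive iff the molecule showed carcinogenicity in at least one
#' experiment, i.e. its label is not the non-carcinogenic sentinel.
#'
#' @param labels data.frame with an `is_sentinel` column (as produced by
#'   [potency_labels()]).
#' @return integer vector of 0/1 labels.
#' @export
binarize_labels <- function(labels) {
  stopifnot(is.data.frame(labels), "is_sentinel" %in% names(labels))
  as.integer(!labels$is_sentinel)
}

#' Build per-molecule potency labels from an experiment table
#'
#' @param records data.frame with columns `molecule_id`, `experiment_id`,
#'   `td50` (`NA` = non-carcinogenic experiment).
#' @param sentinel,base passed to [to_log_potency()].
#' @return data.frame: `molecule_id`, `y`, `is_sentinel`.
#' @export
potency_labels <- function(records, sentinel = -1.62, base = 10) {
  stopifnot(is.data.frame(records),
            all(c("molecule_id", "td50") %in% names(records)))
  ids <- unique(records$molecule_id)
  out <- lapply(ids, function(id) {
    agg <- aggregate_td50(records$td50[records$molecule_id == id])
    lab <- to_log_potency(agg, sentinel = sentinel, base = base)
    data.frame(molecule_id = id, y = lab$y, is_sentinel = lab$is_sentinel,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
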