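# Effect aggregation: collapse an arm's domain-specific Cohen's d estimates
# into a single benefit B = sum_d w_d * Z_d with bound-wise propagated URs.

#' Build a weight scheme for an arm's effects
#'
#' Two presets mirror the standard summaries: `"averaged"` gives every
#' reported effect weight 1/D (D = number of effects reported for that arm),
#' so the aggregate is the mean across reported domains; `"summed"` gives
#' every effect weight 1, so the aggregate is the sum. Subgroup estimates
#' (same domain, different subpopulation) count as separate components.
#'
#' @param kind `"averaged"` or `"summed"`.
#' @param effects Data frame of the arm's effects ([effect_estimate()] rows).
#' @return An object of class `ecd_weight_scheme`: list with `kind` and a
#'   `weights` data frame (`domain`, `subgroup`, `weight`).
#' @examples
#' eff <- rbind(
#'   effect_estimate("cognitive", 0.67, 0.48, 0.86),
#'   effect_estimate("language", 0.51, 0.08, 0.94)
#' )
#' make_scheme("averaged", eff)$weights$weight  # 0.5 0.5
#' @export
make_scheme <- function(kind = c("averaged", "summed"), effects) {
  kind <- match.arg(kind)
  if (is.null(effects) || nrow(effects) == 0) {
    stop("cannot build a weight scheme for an empty effect list")
  }
  d <- nrow(effects)
  w <- if (kind == "averaged") rep(1 / d, d) else rep(1, d)
  weight_scheme(
    data.frame(domain = effects$domain, subgroup = effects$subgroup,
               weight = w, stringsAsFactors = FALSE),
    kind = kind
  )
}

#' Construct a (custom) weight scheme from an explicit weight table
#'
#' @param weights Data frame with columns `domain`, `subgroup` (optional,
#'   defaults to `""`) and `weight`.
#' @param kind Label stored on the scheme; `"custom"` unless called by
#'   [make_scheme()].
#' @return An `ecd_weight_scheme`.
#' @export
weight_scheme <- function(weights, kind = "custom") {
  if (!all(c("domain", "weight") %in% names(weights))) {
    stop("weights must have columns 'domain' and 'weight'")
  }
  if (is.null(weights$subgroup)) weights$subgroup <- ""
  weights$subgroup[is.na(weights$subgroup)] <- ""
  if (any(!is.finite(weights$weight)) || any(weights$weight < 0)) {
    stop("all weights must be finite and >= 0")
  }
  if (!any(weights$weight > 0)) stop("at least one weight must be > 0")
  structure(list(kind = kind,
                 weights = weights[, c("domain", "subgroup", "weight")]),
            class = "ecd_weight_scheme")
}

#' @export
print.ecd_weight_scheme <- function(x, ...) {
  cat(sprintf("<ecd_weight_scheme> kind = %s\n", x$kind))
  print(x$weights, row.names = FALSE)
  invisible(x)
}

#' Aggregate effect estimates under a weight scheme
#'
#' Computes the weighted benefit `B = sum_d w_d * Z_d` and propagates the
#' 95% UR bound-wise: the aggregate lower (upper) bound is the weighted sum
#' of the component lower (upper) bounds. This interval arithmetic — rather
#' than variance-based pooling — is the propagation rule consistent with
#' published league tables for these summaries. All arithmetic is kept at
#' full precision; rounding happens only at display ([round_display()]).
#'
#' @param effects Data frame of effects ([effect_estimate()] rows).
#' @param scheme An `ecd_weight_scheme` covering every (domain, subgroup)
#'   pair present in `effects`.
#' @return An object of class `ecd_aggregate`: list with `point`, `lower`,
#'   `upper` (SD units) and `scheme_kind`.
#' @examples
#' eff <- rbind(
#'   effect_estimate("cognitive", 0.67, 0.48, 0.86),
#'   effect_estimate("expressive_language", 0.97, 0.82, 1.21),
#'   effect_estimate("receptive_language", 0.85, 0.64, 1.03)
#' )
#' aggregate_effects(eff, make_scheme("averaged", eff))  # 0.83 (0.65, 1.03)
#' @export
aggregate_effects <- function(effects, scheme) {
  if (!inherits(scheme, "ecd_weight_scheme")) {
    stop("scheme must be an ecd_weight_scheme (see make_scheme())")
  }
  if (is.null(effects) || nrow(effects) == 0) stop("no effects to aggregate")
  ekeys <- effect_key(effects$domain, effects$subgroup)
  wkeys <- effect_key(scheme$weights$domain, scheme$weights$subgroup)
  idx <- match(ekeys, wkeys)
  if (anyNA(idx)) {
    miss <- effects[is.na(idx), c("domain", "subgroup")]
    stop("no weight provided for effect(s): ",
         paste(ifelse(nzchar(miss$subgroup),
                      paste0(miss$domain, " (", miss$subgroup, ")"),
                      miss$domain), collapse = ", "))
  }
  w <- scheme$weights$weight[idx]
  if (!any(w > 0)) stop("all applicable weights are zero")
  structure(
    list(point = sum(w * effects$estimate),
         lower = sum(w * effects$lower),
         upper = sum(w * effects$upper),
         scheme_kind = scheme$kind),
    class = "ecd_aggregate"
  )
}

#' @export
print.ecd_aggregate <- function(x, ...) {
  cat(sprintf("<ecd_aggregate> %s: %.4f (95%% UR %.4f to %.4f) SD\n",
              x$scheme_kind, x$point, x$lower, x$upper))
  invisible(x)
}
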