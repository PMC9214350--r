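# ICER computation, uncertainty-interval propagation, display rounding,
# ranking, and an optional Monte Carlo interval extension.

#' Point incremental cost-effectiveness ratio
#'
#' `ICER = (C_i - C_0) / (B_i - B_0)`: incremental cost per SD of aggregate
#' developmental gain. The bundled application uses `cost_0 = 0` and
#' `benefit_0 = 0` because study effects and costs are already incremental
#' to each study's own control; explicit baselines are accepted for general
#' use. A smaller ICER means better value for money.
#'
#' @param cost_i,cost_0 Intervention and status-quo costs (US$).
#' @param benefit_i,benefit_0 Intervention and status-quo benefits (SD).
#' @return The ICER at full precision, or `NA` (with attribute
#'   `dominated = TRUE`) when the incremental benefit is <= 0, in which case
#'   no meaningful ratio exists.
#' @examples
#' icer_point(24, 0, 2.49, 0)  # 9.63..., displays as $10
#' @export
icer_point <- function(cost_i, cost_0 = 0, benefit_i, benefit_0 = 0) {
  db <- benefit_i - benefit_0
  if (db <= 0) {
    return(structure(NA_real_, dominated = TRUE))
  }
  (cost_i - cost_0) / db
}

#' 95% uncertainty range of an ICER by interval propagation
#'
#' The effect UR maps inversely onto the ICER UR (cost held fixed): the
#' ICER's lower bound divides by the effect's upper bound and vice versa.
#' Bounds are computed from unrounded aggregates.
#'
#' @param delta_cost Incremental cost (>= 0).
#' @param benefit An `ecd_aggregate` (see [aggregate_effects()]).
#' @return Named numeric `c(lower, upper)`. When the effect's lower bound is
#'   <= 0 the upper ICER bound is `Inf` and the result carries attribute
#'   `unbounded_upper = TRUE`; when the effect's upper bound is <= 0 the
#'   whole interval is undefined (`NA`, attribute `dominated = TRUE`).
#' @examples
#' b <- structure(list(point = 0.83, lower = 0.6467, upper = 1.0333,
#'                     scheme_kind = "averaged"), class = "ecd_aggregate")
#' icer_interval(24, b)  # ~ (23.2, 37.1)
#' @export
icer_interval <- function(delta_cost, benefit) {
  stopifnot(delta_cost >= 0)
  if (benefit$upper <= 0) {
    return(structure(c(lower = NA_real_, upper = NA_real_), dominated = TRUE))
  }
  lo <- delta_cost / benefit$upper
  if (benefit$lower <= 0) {
    return(structure(c(lower = lo, upper = Inf), unbounded_upper = TRUE))
  }
  c(lower = lo, upper = delta_cost / benefit$lower)
}

#' Display rounding
#'
#' Money is shown to the nearest dollar and effects to two decimals; all
#' computation upstream keeps full precision and rounding is applied only
#' here. Ties (exact halves) round to even — the convention recovered from
#' the published tables, where 69/0.40 = 172.5 prints as $172 while
#' 99/0.40 = 247.5 prints as $248. Values within a small relative tolerance
#' of an exact half are snapped to it first, so that binary floating-point
#' representations of decimal inputs do not flip a tie.
#'
#' @param value Numeric vector.
#' @param what `"money"` (0 decimals) or `"effect"` (2 decimals).
#' @return Rounded values; non-finite inputs pass through unchanged.
#' @examples
#' round_display(9.64, "money")        # 10
#' round_display(0.78333, "effect")    # 0.78
#' round_display(c(172.5, 247.5))      # 172, 248
#' @export
round_display <- function(value, what = c("money", "effect")) {
  what <- match.arg(what)
  s <- if (what == "money") 1 else 100
  y <- value * s
  half <- floor(y) + 0.5
  snap <- is.finite(y) & abs(y - half) <= 1e-6 * pmax(1, abs(y))
  y[snap] <- half[snap]
  ifelse(is.finite(y), round(y) / s, y)
}

arm_cost <- function(arm, cost_basis) {
  v <- switch(cost_basis,
              standardized = arm$per_child_standardized,
              local = arm$per_child_local,
              stop("cost_basis must be 'standardized' or 'local'"))
  if (is.na(v)) {
    stop(sprintf("arm '%s' has no %s per-child cost", arm$arm_id, cost_basis))
  }
  v
}

#' Evaluate one arm: aggregate effects and compute its ICER with UR
#'
#' Composes [make_scheme()] (or a supplied custom scheme),
#' [aggregate_effects()], [icer_point()] and [icer_interval()] with a zero
#' status quo by default. Stores unrounded values alongside display forms.
#'
#' @param arm An `ecd_arm`.
#' @param scheme_kind `"averaged"` or `"summed"` (ignored when `scheme` is
#'   given).
#' @param cost_basis `"standardized"` or `"local"`.
#' @param scheme Optional custom `ecd_weight_scheme`.
#' @param cost_0,benefit_0 Status-quo cost and benefit (defaults 0).
#' @return An object of class `ecd_icer`.
#' @export
evaluate_arm <- function(arm, scheme_kind = c("averaged", "summed"),
                         cost_basis = c("standardized", "local"),
                         scheme = NULL, cost_0 = 0, benefit_0 = 0) {
  cost_basis <- match.arg(cost_basis)
  if (is.null(scheme)) {
    scheme_kind <- match.arg(scheme_kind)
    scheme <- make_scheme(scheme_kind, arm$effects)
  }
  agg <- aggregate_effects(arm$effects, scheme)
  cost <- arm_cost(arm, cost_basis)
  point <- icer_point(cost, cost_0, agg$point, benefit_0)
  dominated <- isTRUE(attr(point, "dominated"))
  if (dominated) {
    interval <- c(lower = NA_real_, upper = NA_real_)
    unbounded <- FALSE
  } else {
    interval <- icer_interval(cost - cost_0, agg)
    unbounded <- isTRUE(attr(interval, "unbounded_upper"))
  }
  structure(
    list(
      arm_id = arm$arm_id,
      study_label = arm$study_label,
      scheme_kind = scheme$kind,
      cost_basis = cost_basis,
      cost_per_child = cost,
      effect = agg$point, effect_lower = agg$lower, effect_upper = agg$upper,
      icer = as.numeric(point),
      icer_lower = unname(interval["lower"]),
      icer_upper = unname(interval["upper"]),
      effect_display = unname(round_display(c(agg$point, agg$lower, agg$upper), "effect")),
      icer_display = unname(round_display(c(as.numeric(point), interval), "money")),
      dominated = dominated,
      unbounded_upper = unbounded,
      rank = NA_integer_
    ),
    class = "ecd_icer"
  )
}

#' @export
print.ecd_icer <- function(x, ...) {
  if (x$dominated) {
    cat(sprintf("<ecd_icer> %s [%s/%s]: dominated (aggregate effect <= 0)\n",
                x$arm_id, x$scheme_kind, x$cost_basis))
  } else {
    up <- if (is.finite(x$icer_upper)) {
      sprintf("$%s", format(round_display(x$icer_upper, "money"), big.mark = ","))
    } else "unbounded"
    cat(sprintf("<ecd_icer> %s [%s/%s]: $%s ($%s to %s) per SD\n",
                x$arm_id, x$scheme_kind, x$cost_basis,
                format(round_display(x$icer, "money"), big.mark = ","),
                format(round_display(x$icer_lower, "money"), big.mark = ","), up))
  }
  invisible(x)
}

#' Rank evaluated arms into a league table
#'
#' Dominated arms (aggregate effect <= 0) are excluded from ranking and kept
#' in the `dominated` attribute. Ranking is by ascending unrounded point
#' ICER; ties break by lower per-child cost, then lexicographic `arm_id`.
#'
#' @param results List of `ecd_icer` objects sharing `scheme_kind` and
#'   `cost_basis`.
#' @return An `ecd_league_table`: a data frame with one row per ranked arm
#'   (unrounded and display columns), attributes `scheme_kind`,
#'   `cost_basis`, `dominated`.
#' @export
rank_arms <- function(results) {
  if (inherits(results, "ecd_icer")) results <- list(results)
  if (length(results) == 0) {
    return(empty_league_table("", ""))
  }
  sk <- unique(vapply(results, `[[`, character(1), "scheme_kind"))
  cb <- unique(vapply(results, `[[`, character(1), "cost_basis"))
  if (length(sk) != 1 || length(cb) != 1) {
    stop("all results must share one scheme_kind and one cost_basis")
  }
  dom <- vapply(results, `[[`, logical(1), "dominated")
  ranked <- results[!dom]
  df <- do.call(rbind, lapply(ranked, function(r) {
    data.frame(
      arm_id = r$arm_id, study_label = r$study_label,
      effect = r$effect, effect_lower = r$effect_lower,
      effect_upper = r$effect_upper,
      cost_per_child = r$cost_per_child,
      icer = r$icer, icer_lower = r$icer_lower, icer_upper = r$icer_upper,
      effect_disp = r$effect_display[1], effect_lower_disp = r$effect_display[2],
      effect_upper_disp = r$effect_display[3],
      icer_disp = r$icer_display[1], icer_lower_disp = r$icer_display[2],
      icer_upper_disp = r$icer_display[3],
      unbounded_upper = r$unbounded_upper,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(df)) {
    df <- empty_league_table(sk, cb)
    attr(df, "dominated") <- results[dom]
    return(df)
  }
  ord <- order(df$icer, df$cost_per_child, df$arm_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("rank", setdiff(names(df), "rank"))]
  structure(df, scheme_kind = sk, cost_basis = cb,
            dominated = results[dom],
            class = c("ecd_league_table", "data.frame"))
}

empty_league_table <- function(scheme_kind, cost_basis) {
  df <- data.frame(
    rank = integer(), arm_id = character(), study_label = character(),
    effect = numeric(), effect_lower = numeric(), effect_upper = numeric(),
    cost_per_child = numeric(), icer = numeric(), icer_lower = numeric(),
    icer_upper = numeric(), effect_disp = numeric(),
    effect_lower_disp = numeric(), effect_upper_disp = numeric(),
    icer_disp = numeric(), icer_lower_disp = numeric(),
    icer_upper_disp = numeric(), unbounded_upper = logical(),
    stringsAsFactors = FALSE
  )
  structure(df, scheme_kind = scheme_kind, cost_basis = cost_basis,
            dominated = list(),
            class = c("ecd_league_table", "data.frame"))
}

#' Build a league table straight from a portfolio
#'
#' Evaluates every league-eligible arm under one scheme and cost basis and
#' ranks the results.
#'
#' @param portfolio An `ecd_portfolio`.
#' @param scheme_kind `"averaged"` or `"summed"`.
#' @param cost_basis `"standardized"` or `"local"`.
#' @param weights Optional custom weight table (see [weight_scheme()]);
#'   overrides `scheme_kind`.
#' @param include_ineligible If `TRUE`, rank all arms regardless of the
#'   eligibility flag.
#' @return An `ecd_league_table`.
#' @examples
#' \donttest{
#' lt <- build_league_table(ecd_study_portfolio(), "averaged", "standardized")
#' lt$arm_id[lt$rank == 1]  # "aboud_2013_hv"
#' }
#' @export
build_league_table <- function(portfolio,
                               scheme_kind = c("averaged", "summed"),
                               cost_basis = c("standardized", "local"),
                               weights = NULL,
                               include_ineligible = FALSE) {
  scheme_kind <- match.arg(scheme_kind)
  cost_basis <- match.arg(cost_basis)
  arms <- unclass(portfolio)
  if (!include_ineligible) {
    arms <- Filter(function(a) a$league_eligible, arms)
  }
  if (length(arms) == 0) {
    return(empty_league_table(scheme_kind, cost_basis))
  }
  results <- lapply(arms, function(a) {
    scheme <- if (is.null(weights)) NULL else weight_scheme(weights)
    evaluate_arm(a, scheme_kind, cost_basis, scheme = scheme)
  })
  rank_arms(unname(results))
}

money_fmt <- function(x) {
  ifelse(is.finite(x), paste0("$", format(x, big.mark = ",", trim = TRUE,
                                          scientific = FALSE)), "unbounded")
}

#' Render a league table as markdown
#'
#' Columns mirror the conventional published layout: study, effect estimate
#' with UR, cost per child, rank, ICER with UR.
#'
#' @param lt An `ecd_league_table`.
#' @return Character vector of markdown lines.
#' @export
league_markdown <- function(lt) {
  hdr <- c("Study", "Effect estimate", "Cost per child", "Rank",
           "Cost-effectiveness (ICER)")
  rows <- lapply(seq_len(nrow(lt)), function(i) {
    r <- lt[i, ]
    c(r$study_label,
      sprintf("%.2f (%.2f to %.2f)", r$effect_disp, r$effect_lower_disp,
              r$effect_upper_disp),
      money_fmt(r$cost_per_child),
      as.character(r$rank),
      sprintf("%s (%s to %s)", money_fmt(r$icer_disp),
              money_fmt(r$icer_lower_disp), money_fmt(r$icer_upper_disp)))
  })
  tab <- do.call(rbind, c(list(hdr), rows))
  widths <- apply(nchar(tab), 2, max)
  fmt_row <- function(cells) {
    padded <- mapply(function(cell, w) formatC(cell, width = w, flag = "-"),
                     cells, widths)
    paste0("| ", paste(padded, collapse = " | "), " |")
  }
  sep <- paste0("|", paste(vapply(widths + 2, function(w)
    paste(rep("-", w), collapse = ""), character(1)), collapse = "|"), "|")
  c(sprintf("League table — %s effect estimate, %s cost",
            attr(lt, "scheme_kind"), attr(lt, "cost_basis")),
    "", fmt_row(tab[1, ]), sep,
    vapply(seq_len(nrow(lt)), function(i) fmt_row(tab[i + 1, ]), character(1)))
}

#' @export
print.ecd_league_table <- function(x, ...) {
  if (nrow(x) == 0) {
    cat(sprintf("<ecd_league_table> empty (%s/%s)\n",
                attr(x, "scheme_kind"), attr(x, "cost_basis")))
  } else {
    cat(league_markdown(x), sep = "\n")
  }
  ndom <- length(attr(x, "dominated"))
  if (ndom > 0) {
    cat(sprintf("\n%d dominated arm(s) excluded from ranking: %s\n", ndom,
                paste(vapply(attr(x, "dominated"), `[[`, character(1),
                             "arm_id"), collapse = ", ")))
  }
  invisible(x)
}

#' Write a league table to CSV, JSON or markdown
#'
#' @param lt An `ecd_league_table`.
#' @param path Output path; `NULL` writes to stdout.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_league_table <- function(lt, path = NULL,
                               format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  df <- as.data.frame(lt)
  if (format == "csv") {
    if (is.null(path)) {
      utils::write.csv(df, stdout(), row.names = FALSE)
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else if (format == "json") {
    payload <- list(scheme_kind = attr(lt, "scheme_kind"),
                    cost_basis = attr(lt, "cost_basis"),
                    rows = df,
                    dominated = vapply(attr(lt, "dominated"), `[[`,
                                       character(1), "arm_id"))
    txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, na = "null")
    if (is.null(path)) cat(txt, "\n") else writeLines(txt, path)
  } else {
    lines <- league_markdown(lt)
    if (is.null(path)) cat(lines, sep = "\n") else writeLines(lines, path)
  }
  invisible(path)
}

#' Monte Carlo uncertainty interval for an arm's ICER (extension)
#'
#' This is an extension beyond the published interval arithmetic: each
#' effect is sampled independently from
#' `Normal(estimate, (upper - lower)/3.92)` (the UR read as a 95% normal
#' interval), aggregated per draw under the chosen scheme, and the fixed
#' per-child cost divided by each positive aggregate. The empirical 2.5th
#' and 97.5th percentiles of those ratios form the interval. Draws with
#' non-positive aggregates are counted in the `n_nonpositive` attribute
#' (and trigger a message) rather than being dropped silently.
#'
#' @param arm An `ecd_arm`.
#' @param scheme_kind `"averaged"` or `"summed"`.
#' @param cost_basis `"standardized"` or `"local"`.
#' @param n_samples Number of draws (>= 100).
#' @param seed Integer seed; mandatory, for reproducibility.
#' @return Named numeric `c(lower, upper)` with attributes `n_nonpositive`
#'   and `note = "extension"`.
#' @export
monte_carlo_interval <- function(arm, scheme_kind = c("averaged", "summed"),
                                 cost_basis = c("standardized", "local"),
                                 n_samples = 10000, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is required: Monte Carlo intervals must be reproducible")
  }
  stopifnot(n_samples >= 100)
  scheme_kind <- match.arg(scheme_kind)
  cost_basis <- match.arg(cost_basis)
  eff <- arm$effects
  if (any(eff$upper < eff$lower)) stop("effect URs must have lower <= upper")
  sds <- (eff$upper - eff$lower) / 3.92
  w <- make_scheme(scheme_kind, eff)$weights$weight
  cost <- arm_cost(arm, cost_basis)
  d <- nrow(eff)
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(d * n_samples, mean = eff$estimate, sd = sds),
                  nrow = d)
  agg <- as.numeric(crossprod(w, draws))
  pos <- agg > 0
  if (!any(pos)) stop("all Monte Carlo draws gave non-positive aggregates")
  q <- stats::quantile(cost / agg[pos], c(0.025, 0.975), names = FALSE)
  if (sum(!pos) > 0) {
    message(sprintf("monte_carlo_interval: %d of %d draws had non-positive aggregate effects and were excluded",
                    sum(!pos), n_samples))
  }
  structure(c(lower = q[1], upper = q[2]),
            n_nonpositive = sum(!pos), note = "extension")
}
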