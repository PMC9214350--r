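#' Recognised developmental domains
#'
#' Developmental assessments of children under 3 conventionally cover four
#' areas: motor (gross/fine), cognitive, language (expressive/receptive) and
#' socioemotional skills. Effects are recorded against one of these labels;
#' the generic `motor` and `language` labels are used when a study does not
#' split the domain.
#'
#' @format Character vector of the eight accepted domain labels.
#' @export
ecd_domains <- c(
  "cognitive", "language", "expressive_language", "receptive_language",
  "fine_motor", "gross_motor", "motor", "socioemotional"
)

effect_key <- function(domain, subgroup) paste(domain, subgroup, sep = "\r")

#' Create a domain-specific effect estimate
#'
#' One Cohen's d effect (standardized mean difference relative to the study
#' control, in pooled-SD units) for one developmental domain, together with
#' its 95% uncertainty range (UR) as reported.
#'
#' The ordering constraint `lower <= estimate <= upper` is non-strict:
#' published tables occasionally print an interval endpoint equal to the
#' point estimate and such rows are stored as printed.
#'
#' @param domain One of [ecd_domains].
#' @param estimate Point estimate (SD units).
#' @param lower,upper 95% UR bounds (SD units).
#' @param significant Logical; statistical significance as reported.
#' @param subgroup Optional free-text qualifier (e.g. "iron-deficient") used
#'   when a study reports the same domain for distinct subpopulations.
#' @return A one-row data frame with columns `domain`, `subgroup`,
#'   `estimate`, `lower`, `upper`, `significant`.
#' @examples
#' effect_estimate("cognitive", 0.40, 0.10, 0.69, significant = TRUE)
#' @export
effect_estimate <- function(domain, estimate, lower, upper,
                            significant = NA, subgroup = "") {
  data.frame(
    domain = as.character(domain),
    subgroup = as.character(subgroup),
    estimate = as.numeric(estimate),
    lower = as.numeric(lower),
    upper = as.numeric(upper),
    significant = as.logical(significant),
    stringsAsFactors = FALSE
  )
}

#' Create an intervention arm
#'
#' An arm bundles one intervention's costs with its reported effects. Costs
#' are carried on two bases: `per_child_local` is the per-child cost in the
#' study's own country and year (US$), and `per_child_standardized` is the
#' hypothetical per-child cost had the intervention been run in a typical
#' low/middle-income country in the reference year (see the costing
#' functions). Effects are control-relative, so downstream ICERs use a zero
#' status quo by default.
#'
#' @param arm_id Unique identifier within a portfolio.
#' @param study_label Citation-style label for display.
#' @param country Country (or countries) of the study.
#' @param study_year Calendar year or year range, as character.
#' @param effects Data frame of effects as built by [effect_estimate()]
#'   (rows may be concatenated with `rbind`).
#' @param year_imputed Logical; `TRUE` when the study year was not stated
#'   and was imputed as the year prior to publication.
#' @param total_cost Total intervention cost (US$), `NA` if unreported.
#' @param per_child_local,per_child_standardized Per-child costs (US$).
#' @param n_children Number of children targeted, `NA` if unreported.
#' @param league_eligible Logical; whether the arm participates in league
#'   tables (arms lacking usable cost or effect data are carried but
#'   excluded from ranking).
#' @return An object of class `ecd_arm`.
#' @examples
#' arm <- intervention_arm(
#'   "demo", "Demo et al, 2020", "Demoland", "2019",
#'   effects = effect_estimate("cognitive", 0.5, 0.2, 0.8, TRUE),
#'   per_child_local = 10, per_child_standardized = 40
#' )
#' @export
intervention_arm <- function(arm_id, study_label, country, study_year,
                             effects,
                             year_imputed = FALSE,
                             total_cost = NA_real_,
                             per_child_local = NA_real_,
                             per_child_standardized = NA_real_,
                             n_children = NA_real_,
                             league_eligible = TRUE) {
  structure(
    list(
      arm_id = as.character(arm_id),
      study_label = as.character(study_label),
      country = as.character(country),
      study_year = as.character(study_year),
      year_imputed = isTRUE(year_imputed),
      total_cost = as.numeric(total_cost),
      per_child_local = as.numeric(per_child_local),
      per_child_standardized = as.numeric(per_child_standardized),
      n_children = as.numeric(n_children),
      league_eligible = isTRUE(league_eligible),
      effects = effects
    ),
    class = "ecd_arm"
  )
}

#' Assemble a portfolio of intervention arms
#'
#' @param arms List of [intervention_arm()] objects.
#' @return An object of class `ecd_portfolio` (a named list of arms).
#' @export
ecd_portfolio <- function(arms) {
  if (!is.list(arms)) stop("arms must be a list of intervention arms")
  nm <- vapply(arms, function(a) a$arm_id, character(1))
  structure(stats::setNames(arms, nm), class = "ecd_portfolio")
}

#' @export
print.ecd_arm <- function(x, ...) {
  cat(sprintf("<ecd_arm> %s — %s (%s, %s%s)\n", x$arm_id, x$study_label,
              x$country, x$study_year, if (x$year_imputed) ", imputed" else ""))
  cat(sprintf("  cost/child: local $%s, standardized $%s; league eligible: %s\n",
              format(x$per_child_local), format(x$per_child_standardized),
              x$league_eligible))
  cat(sprintf("  %d effect(s): %s\n", nrow(x$effects),
              paste(ifelse(nzchar(x$effects$subgroup),
                           paste0(x$effects$domain, " (", x$effects$subgroup, ")"),
                           x$effects$domain), collapse = ", ")))
  invisible(x)
}

#' @export
print.ecd_portfolio <- function(x, ...) {
  cat(sprintf("<ecd_portfolio> %d arm(s), %d league-eligible\n", length(x),
              sum(vapply(x, function(a) a$league_eligible, logical(1)))))
  for (a in x) {
    cat(sprintf("  %-20s %-36s %2d effect(s)\n", a$arm_id, a$study_label,
                nrow(a$effects)))
  }
  invisible(x)
}

finding <- function(arm_id, field, message) {
  data.frame(arm_id = arm_id, field = field, message = message,
             stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(arm_id = character(), field = character(), message = character(),
             stringsAsFactors = FALSE)
}

validate_arm <- function(arm) {
  out <- list()
  eff <- arm$effects
  if (is.null(eff) || nrow(eff) == 0) {
    return(finding(arm$arm_id, "effects", "arm has no effect estimates"))
  }
  bad_domain <- !(eff$domain %in% ecd_domains)
  for (i in which(bad_domain)) {
    out[[length(out) + 1L]] <- finding(
      arm$arm_id, sprintf("effects[%d].domain", i),
      sprintf("unknown domain label '%s'", eff$domain[i]))
  }
  keys <- effect_key(eff$domain, eff$subgroup)
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    for (k in dup) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- finding(
        arm$arm_id, "effects",
        sprintf("duplicate (domain, subgroup) pair ('%s', '%s')",
                parts[1], if (length(parts) > 1) parts[2] else ""))
    }
  }
  for (i in seq_len(nrow(eff))) {
    vals <- c(eff$estimate[i], eff$lower[i], eff$upper[i])
    fld <- sprintf("effects[%d]", i)
    if (any(!is.finite(vals))) {
      out[[length(out) + 1L]] <- finding(
        arm$arm_id, fld, "estimate and UR bounds must all be finite")
    } else if (eff$lower[i] > eff$estimate[i] || eff$estimate[i] > eff$upper[i]) {
      out[[length(out) + 1L]] <- finding(
        arm$arm_id, fld,
        sprintf("UR ordering violated: require lower <= estimate <= upper, got (%g, %g, %g)",
                eff$lower[i], eff$estimate[i], eff$upper[i]))
    }
  }
  for (fld in c("total_cost", "per_child_local", "per_child_standardized")) {
    v <- arm[[fld]]
    if (!is.na(v) && v < 0) {
      out[[length(out) + 1L]] <- finding(
        arm$arm_id, fld, sprintf("money amount must be >= 0, got %g", v))
    }
  }
  if (!is.na(arm$total_cost) && !is.na(arm$n_children) &&
      !is.na(arm$per_child_local) && arm$n_children >= 1) {
    if (abs(arm$total_cost / arm$n_children - arm$per_child_local) > 0.5) {
      out[[length(out) + 1L]] <- finding(
        arm$arm_id, "per_child_local",
        sprintf("total_cost/n_children = %g disagrees with per_child_local = %g by more than $0.50",
                arm$total_cost / arm$n_children, arm$per_child_local))
    }
  }
  if (length(out) == 0) return(no_findings())
  do.call(rbind, out)
}

#' Validate a portfolio against the data-model invariants
#'
#' Checks every arm for: a non-empty effect list, recognised domain labels,
#' unique (domain, subgroup) pairs, finite and ordered UR bounds
#' (`lower <= estimate <= upper`, non-strict), non-negative money amounts,
#' and agreement between `total_cost / n_children` and `per_child_local`
#' (within $0.50) when both are present; plus portfolio-level uniqueness of
#' `arm_id`. Violations are returned as findings, not raised as errors.
#'
#' @param portfolio An `ecd_portfolio` or plain list of `ecd_arm` objects.
#' @return Data frame with columns `arm_id`, `field`, `message`; zero rows
#'   when the portfolio is fully valid.
#' @export
validate_portfolio <- function(portfolio) {
  arms <- unclass(portfolio)
  out <- lapply(arms, validate_arm)
  ids <- vapply(arms, function(a) a$arm_id, character(1))
  if (anyDuplicated(ids)) {
    for (d in unique(ids[duplicated(ids)])) {
      out[[length(out) + 1L]] <- finding(
        d, "arm_id", sprintf("arm_id '%s' is not unique within the portfolio", d))
    }
  }
  res <- do.call(rbind, c(list(no_findings()), out))
  rownames(res) <- NULL
  res
}

# ---- long-format (CSV) serialization ---------------------------------------

portfolio_long_columns <- c(
  "arm_id", "study_label", "country", "study_year", "year_imputed",
  "total_cost", "per_child_local", "per_child_standardized",
  "league_eligible", "domain", "subgroup", "estimate", "lower", "upper",
  "significant"
)

#' Convert a portfolio to/from long format
#'
#' The long format has one row per effect estimate, with the arm-level
#' columns repeated; it is the on-disk CSV schema.
#'
#' @param x An `ecd_portfolio`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data frame in long format.
#' @export
as.data.frame.ecd_portfolio <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(unclass(x), function(a) {
    eff <- a$effects
    data.frame(
      arm_id = a$arm_id, study_label = a$study_label, country = a$country,
      study_year = a$study_year, year_imputed = a$year_imputed,
      total_cost = a$total_cost, per_child_local = a$per_child_local,
      per_child_standardized = a$per_child_standardized,
      league_eligible = a$league_eligible,
      domain = eff$domain, subgroup = eff$subgroup,
      estimate = eff$estimate, lower = eff$lower, upper = eff$upper,
      significant = eff$significant,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a portfolio from a long-format data frame
#'
#' @param df Data frame with the columns described in
#'   [as.data.frame.ecd_portfolio()].
#' @return An `ecd_portfolio`.
#' @export
portfolio_from_long <- function(df) {
  missing_cols <- setdiff(portfolio_long_columns, names(df))
  if (length(missing_cols)) {
    stop("portfolio data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$subgroup[is.na(df$subgroup)] <- ""
  pieces <- split(df, factor(df$arm_id, levels = unique(df$arm_id)))
  arms <- lapply(pieces, function(p) {
    intervention_arm(
      arm_id = p$arm_id[1], study_label = p$study_label[1],
      country = p$country[1], study_year = as.character(p$study_year[1]),
      year_imputed = isTRUE(p$year_imputed[1]),
      total_cost = p$total_cost[1],
      per_child_local = p$per_child_local[1],
      per_child_standardized = p$per_child_standardized[1],
      league_eligible = isTRUE(p$league_eligible[1]),
      effects = effect_estimate(p$domain, p$estimate, p$lower, p$upper,
                                p$significant, p$subgroup)
    )
  })
  ecd_portfolio(unname(arms))
}

#' Read / write portfolios as CSV or JSON
#'
#' CSV uses the long format (one row per effect, UTF-8, "." decimal
#' separator); JSON stores one object per arm with a nested `effects`
#' array. Both round-trip at full precision.
#'
#' @param path File path.
#' @param portfolio An `ecd_portfolio`.
#' @return The portfolio (readers), or `path` invisibly (writers).
#' @export
read_portfolio_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(study_year = "character",
                                       subgroup = "character",
                                       domain = "character"))
  portfolio_from_long(df)
}

#' @rdname read_portfolio_csv
#' @export
write_portfolio_csv <- function(portfolio, path) {
  utils::write.csv(as.data.frame(portfolio), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_portfolio_csv
#' @export
write_portfolio_json <- function(portfolio, path) {
  arms <- lapply(unclass(portfolio), function(a) {
    list(
      arm_id = a$arm_id, study_label = a$study_label, country = a$country,
      study_year = a$study_year, year_imputed = a$year_imputed,
      total_cost = a$total_cost, per_child_local = a$per_child_local,
      per_child_standardized = a$per_child_standardized,
      n_children = a$n_children,
      league_eligible = a$league_eligible,
      effects = a$effects
    )
  })
  jsonlite::write_json(unname(arms), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname read_portfolio_csv
#' @export
read_portfolio_json <- function(path) {
  arms <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  built <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    eff <- arms$effects[[i]]
    eff$subgroup[is.na(eff$subgroup)] <- ""
    intervention_arm(
      arm_id = a$arm_id, study_label = a$study_label, country = a$country,
      study_year = a$study_year, year_imputed = isTRUE(a$year_imputed),
      total_cost = if (is.null(a$total_cost)) NA_real_ else a$total_cost,
      per_child_local = a$per_child_local,
      per_child_standardized = a$per_child_standardized,
      n_children = if (is.null(a$n_children)) NA_real_ else a$n_children,
      league_eligible = isTRUE(a$league_eligible),
      effects = effect_estimate(eff$domain, eff$estimate, eff$lower,
                                eff$upper, eff$significant, eff$subgroup)
    )
  })
  ecd_portfolio(built)
}
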