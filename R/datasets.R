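# Bundled fixtures: the 16-arm study portfolio and the published reference
# league tables it must reproduce.

# md5 of the installed portfolio CSV; verified at load so silent corruption
# of the fixture cannot masquerade as a computation bug.
.ecd_portfolio_md5 <- "a457a634dae8f6e79288d1e57c8a167e"

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ecdcea")
  if (!nzchar(p)) stop("bundled fixture '", file, "' not found")
  p
}

#' Load the bundled study portfolio
#'
#' Returns the 16 intervention arms (from 15 published studies of early
#' parenting and at-home psychosocial stimulation interventions for children
#' under 2 in low/middle-income countries, 1991-2012) exactly as printed in
#' the source tables: domain-specific Cohen's d effects with 95% URs and
#' significance flags, local and LMIC-standardized per-child costs,
#' countries, study years with imputation flags, and the league-eligibility
#' flag marking the 12 arms that enter ranked league tables. Values are
#' stored as printed, including one interval whose lower bound equals its
#' point estimate and the subgroup-split cognitive rows.
#'
#' The fixture's md5 checksum is verified at load.
#'
#' @return An `ecd_portfolio` of 16 arms.
#' @examples
#' \donttest{
#' pf <- ecd_study_portfolio()
#' length(pf)  # 16
#' }
#' @export
ecd_study_portfolio <- function() {
  path <- fixture_path("ecd_portfolio.csv")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .ecd_portfolio_md5)) {
    stop("bundled portfolio fixture failed its checksum (expected ",
         .ecd_portfolio_md5, ", got ", md5, "); reinstall the package")
  }
  read_portfolio_csv(path)
}

#' Published reference league-table values
#'
#' The printed league tables the package reproduces: for each scheme
#' (averaged, summed) and cost basis (standardized, local), the
#' display-rounded effect estimate with UR, cost per child, rank and ICER
#' with UR for the 12 eligible arms.
#'
#' @param scheme Optional filter: `"averaged"` or `"summed"`.
#' @param cost_basis Optional filter: `"standardized"` or `"local"`.
#' @return Data frame of reference rows.
#' @export
reference_league_table <- function(scheme = NULL, cost_basis = NULL) {
  df <- utils::read.csv(fixture_path("ecd_league_reference.csv"),
                        stringsAsFactors = FALSE)
  if (!is.null(scheme)) df <- df[df$scheme == scheme, , drop = FALSE]
  if (!is.null(cost_basis)) df <- df[df$cost_basis == cost_basis, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Recompute the league tables and diff them against the published values
#'
#' For every requested scheme/basis block, builds the league table from the
#' bundled portfolio (or a supplied one) and compares each display-rounded
#' cell — effect point and bounds, cost per child, ICER point and bounds,
#' and rank — against the published reference.
#'
#' @param schemes Schemes to check (default both).
#' @param bases Cost bases to check (default both).
#' @param portfolio Portfolio to evaluate (default the bundled fixture;
#'   passing a perturbed portfolio localizes exactly the affected cells).
#' @return An `ecd_replication`: list with `matched`/`total` counts per cell
#'   category, a `mismatches` data frame (zero rows on success) and
#'   `passed`.
#' @export
replicate_reference <- function(schemes = c("averaged", "summed"),
                                bases = c("standardized", "local"),
                                portfolio = ecd_study_portfolio()) {
  ref <- reference_league_table()
  mism <- list()
  counts <- c(icer = 0L, bound = 0L, rank = 0L, effect = 0L, cost = 0L)
  totals <- c(icer = 0L, bound = 0L, rank = 0L, effect = 0L, cost = 0L)
  note_cell <- function(scheme, basis, arm, cell, expected, got) {
    data.frame(scheme = scheme, cost_basis = basis, arm_id = arm,
               cell = cell, expected = expected, got = got,
               stringsAsFactors = FALSE)
  }
  for (s in schemes) {
    for (b in bases) {
      lt <- build_league_table(portfolio, s, b)
      rf <- ref[ref$scheme == s & ref$cost_basis == b, , drop = FALSE]
      for (i in seq_len(nrow(rf))) {
        r <- rf[i, ]
        j <- which(lt$arm_id == r$arm_id)
        if (length(j) != 1) {
          mism[[length(mism) + 1L]] <- note_cell(s, b, r$arm_id, "presence",
                                                "in league table", "absent")
          totals <- totals + c(icer = 1L, bound = 2L, rank = 1L, effect = 3L,
                               cost = 1L)
          next
        }
        row <- lt[j, ]
        check <- function(cell, cat, expected, got) {
          totals[cat] <<- totals[cat] + 1L
          if (isTRUE(all.equal(expected, got, tolerance = 1e-9))) {
            counts[cat] <<- counts[cat] + 1L
          } else {
            mism[[length(mism) + 1L]] <<- note_cell(s, b, r$arm_id, cell,
                                                    format(expected),
                                                    format(got))
          }
        }
        check("icer", "icer", r$icer, row$icer_disp)
        check("icer_lower", "bound", r$icer_lower, row$icer_lower_disp)
        check("icer_upper", "bound", r$icer_upper, row$icer_upper_disp)
        check("rank", "rank", as.integer(r$rank), as.integer(row$rank))
        check("effect", "effect", r$effect, row$effect_disp)
        check("effect_lower", "effect", r$effect_lower, row$effect_lower_disp)
        check("effect_upper", "effect", r$effect_upper, row$effect_upper_disp)
        check("cost_per_child", "cost", r$cost_per_child, row$cost_per_child)
      }
    }
  }
  mismatches <- if (length(mism)) do.call(rbind, mism) else
    data.frame(scheme = character(), cost_basis = character(),
               arm_id = character(), cell = character(),
               expected = character(), got = character(),
               stringsAsFactors = FALSE)
  structure(
    list(matched = counts, total = totals, mismatches = mismatches,
         passed = nrow(mismatches) == 0),
    class = "ecd_replication"
  )
}

#' @export
print.ecd_replication <- function(x, ...) {
  cat(sprintf(
    "%d/%d ICER points, %d/%d UR bounds, %d/%d ranks, %d/%d effect cells, %d/%d costs matched\n",
    x$matched["icer"], x$total["icer"], x$matched["bound"], x$total["bound"],
    x$matched["rank"], x$total["rank"], x$matched["effect"],
    x$total["effect"], x$matched["cost"], x$total["cost"]))
  if (!x$passed) {
    cat("mismatched cells:\n")
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}
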