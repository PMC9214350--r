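# Ingredients-based unit costing and cross-country/cross-year cost
# standardization. Study costs arise in different countries and years; to
# compare them they are (a) inflated to a common reference year with a
# consumer price index and (b) workforce costs are re-referenced to a common
# annual-wage anchor (the 2010 LMIC average GDP per capita, US$3549).
# Non-workforce inputs (books, toys, ...) are passed through unchanged, as
# their estimates are taken to be already standardized across interventions.

#' Cost-standardization parameters
#'
#' @param cpi_table Data frame with columns `country`, `year`, `cpi` (index
#'   values, any base, > 0).
#' @param local_wage_table Data frame with columns `country`, `year`, `wage`
#'   (annual wage in US$/person-year, > 0); must cover
#'   (`country`, `reference_year`) for every country to be standardized.
#' @param reference_year Calendar year costs are expressed in (default 2010).
#' @param reference_wage Annual wage anchor in US$/person-year (default
#'   3549, the 2010 average GDP per capita across LMICs).
#' @return An object of class `ecd_standardization_params`.
#' @export
standardization_params <- function(cpi_table, local_wage_table,
                                   reference_year = 2010,
                                   reference_wage = 3549) {
  stopifnot(all(c("country", "year", "cpi") %in% names(cpi_table)),
            all(c("country", "year", "wage") %in% names(local_wage_table)))
  if (!is.numeric(reference_wage) || reference_wage <= 0) {
    stop("reference_wage must be > 0")
  }
  if (any(cpi_table$cpi <= 0)) stop("all CPI index values must be > 0")
  if (any(local_wage_table$wage <= 0)) stop("all wages must be > 0")
  structure(
    list(reference_year = as.integer(reference_year),
         reference_wage = as.numeric(reference_wage),
         cpi_table = cpi_table,
         local_wage_table = local_wage_table),
    class = "ecd_standardization_params"
  )
}

lookup_table <- function(tbl, value_col, country, year, what) {
  hit <- tbl$country == country & tbl$year == year
  if (!any(hit)) {
    stop(sprintf("no %s entry for (country = '%s', year = %s)",
                 what, country, year))
  }
  tbl[[value_col]][which(hit)[1]]
}

#' Unit cost per child
#'
#' @param total_cost Total intervention cost (>= 0).
#' @param n_children Number of children targeted (>= 1).
#' @return `total_cost / n_children` at full precision.
#' @examples
#' unit_cost_per_child(167228, 77)  # ~2172
#' @export
unit_cost_per_child <- function(total_cost, n_children) {
  if (any(n_children == 0)) stop("no beneficiaries: n_children must be >= 1")
  stopifnot(all(total_cost >= 0), all(n_children >= 1))
  total_cost / n_children
}

#' Inflate an amount to the reference year via CPI
#'
#' @param amount Money amount in (`country`, `year_from`) terms (>= 0).
#' @param country Country label; must appear in the CPI table for both
#'   `year_from` and the reference year.
#' @param year_from Year the amount is expressed in.
#' @param params An [standardization_params()] object.
#' @return `amount * cpi(country, reference_year) / cpi(country, year_from)`.
#' @export
inflate_to_reference <- function(amount, country, year_from, params) {
  cpi_from <- lookup_table(params$cpi_table, "cpi", country, year_from, "CPI")
  cpi_to <- lookup_table(params$cpi_table, "cpi", country,
                         params$reference_year, "CPI")
  amount * cpi_to / cpi_from
}

#' Standardized unit cost per child from an ingredients list
#'
#' Workforce ingredients are inflated to the reference year and then scaled
#' by `reference_wage / local_wage(country, reference_year)`, re-expressing
#' staff costs at the common wage anchor. Non-workforce ingredients pass
#' through unchanged. The sum is divided by the number of children targeted.
#'
#' Both steps are multiplicative, so standardization is additive over
#' ingredient lists and homogeneous of degree 1 in the amounts.
#'
#' @param ingredients Data frame with columns `name`, `category`
#'   (`"workforce"` or `"non_workforce"`) and `amount` (>= 0).
#' @param country,cost_year Where/when the amounts are expressed.
#' @param n_children Number of children targeted (>= 1).
#' @param params An [standardization_params()] object.
#' @return Standardized cost per child in reference-year US$.
#' @export
standardize_unit_cost <- function(ingredients, country, cost_year,
                                  n_children, params) {
  if (is.null(ingredients) || nrow(ingredients) == 0) {
    stop("empty ingredient list")
  }
  if (!all(ingredients$category %in% c("workforce", "non_workforce"))) {
    stop("ingredient category must be 'workforce' or 'non_workforce'")
  }
  if (any(ingredients$amount < 0)) stop("ingredient amounts must be >= 0")
  if (n_children < 1) stop("no beneficiaries: n_children must be >= 1")
  wf <- ingredients$category == "workforce"
  wf_total <- 0
  if (any(wf)) {
    inflated <- inflate_to_reference(sum(ingredients$amount[wf]), country,
                                     cost_year, params)
    local_wage <- lookup_table(params$local_wage_table, "wage", country,
                               params$reference_year, "wage")
    wf_total <- inflated * params$reference_wage / local_wage
  }
  (wf_total + sum(ingredients$amount[!wf])) / n_children
}

#' Read an ingredients CSV
#'
#' Columns: `arm_id`, `ingredient_name`, `category`, `amount`, `country`,
#' `cost_year`, and optionally `n_children` (defaults to 1, i.e. amounts
#' already per child).
#'
#' @param path File path.
#' @return Data frame of ingredients.
#' @export
read_ingredients_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("arm_id", "ingredient_name", "category", "amount", "country",
            "cost_year")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("ingredients file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$n_children)) df$n_children <- 1
  df
}

#' Read standardization parameters from JSON or YAML
#'
#' The file holds `reference_year`, `reference_wage`, `cpi_table`
#' (country -> year -> index) and `local_wage_table` (country -> year ->
#' wage). YAML files (`.yaml`/`.yml`) require the `yaml` package.
#'
#' @param path File path.
#' @return An [standardization_params()] object.
#' @export
read_standardization_params <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML parameters requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  nested_to_df <- function(x, value_col) {
    rows <- lapply(names(x), function(ctry) {
      yrs <- x[[ctry]]
      data.frame(country = ctry, year = as.integer(names(yrs)),
                 value = as.numeric(unlist(yrs)), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    names(out)[names(out) == "value"] <- value_col
    out
  }
  standardization_params(
    cpi_table = nested_to_df(raw$cpi_table, "cpi"),
    local_wage_table = nested_to_df(raw$local_wage_table, "wage"),
    reference_year = raw$reference_year,
    reference_wage = raw$reference_wage
  )
}

#' Standardize per-child costs for every arm in an ingredients table
#'
#' @param ingredients Data frame as returned by [read_ingredients_csv()].
#' @param params An [standardization_params()] object.
#' @return Data frame with one row per `arm_id`: `country`, `cost_year`,
#'   `n_children`, `unit_cost` (unstandardized per child) and
#'   `standardized_unit_cost`.
#' @export
standardize_costs <- function(ingredients, params) {
  pieces <- split(ingredients,
                  factor(ingredients$arm_id, levels = unique(ingredients$arm_id)))
  rows <- lapply(pieces, function(p) {
    ing <- data.frame(name = p$ingredient_name, category = p$category,
                      amount = p$amount, stringsAsFactors = FALSE)
    n <- p$n_children[1]
    data.frame(
      arm_id = p$arm_id[1], country = p$country[1], cost_year = p$cost_year[1],
      n_children = n,
      unit_cost = unit_cost_per_child(sum(p$amount), n),
      standardized_unit_cost = standardize_unit_cost(
        ing, p$country[1], p$cost_year[1], n, params),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
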