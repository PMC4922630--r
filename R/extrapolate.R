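#' Read population counts
#'
#' @param path CSV with columns `sex`, `group`, `age`, `count` (persons),
#'   one row per combination, e.g. single-year-of-age census counts.
#' @return Validated data frame.
#' @export
read_population_counts <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_population_counts(pop)
}

validate_population_counts <- function(pop) {
  need <- c("sex", "group", "age", "count")
  miss <- setdiff(need, names(pop))
  if (length(miss)) stop("population counts missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(pop$count < 0)) stop("population counts must be nonnegative")
  if (anyDuplicated(pop[c("sex", "group", "age")])) {
    stop("population counts must have one row per (sex, group, age)")
  }
  pop
}

#' Synthetic single-year-of-age population counts
#'
#' A smooth age pyramid (slowly declining counts with age) mimicking the
#' shape of a national civilian noninstitutionalized population, for use as
#' a test fixture; synthetic, with no demographic meaning.
#'
#' @param sex,group Labels for the emitted stratum.
#' @param base Count at age 2.
#' @param ages Age grid.
#' @return Data frame with columns `sex`, `group`, `age`, `count`.
#' @export
synthetic_population_counts <- function(sex = "female", group = "GroupA",
                                        base = 3e5, ages = 2:80) {
  data.frame(sex = sex, group = group, age = ages,
             count = round(base * exp(-0.012 * (ages - 2))))
}

#' Net numbers of people transitioning, from census counts
#'
#' Converts net transition probabilities into net numbers of persons
#' transitioning per year: for each age and boundary, the net probability
#' times the prevalence of the favored direction's origin category times
#' the population count at that age.
#'
#' @param table A `net_transition_table` (CI columns carried through if
#'   present).
#' @param curve The `prevalence_curve` the table was built from.
#' @param pop Population counts covering the table's ages (see
#'   [read_population_counts()]); filtered to `sex`/`group` if those are
#'   identifiable from `curve$stratum` and present in `pop`.
#' @return The table with columns `origin_prev`, `pop_count`, `net_count`
#'   (unrounded) and `net_persons` (rounded).
#' @export
extrapolate_counts <- function(table, curve, pop) {
  pop <- validate_population_counts(pop)
  for (v in c("sex", "group")) {
    if (!is.null(curve$stratum[[v]]) && v %in% names(pop)) {
      pop <- pop[pop[[v]] == curve$stratum[[v]], , drop = FALSE]
    }
  }
  missing_ages <- setdiff(unique(table$age), pop$age)
  if (length(missing_ages)) {
    stop("population counts missing for age(s): ",
         paste(sort(missing_ages), collapse = ", "))
  }
  origin_cat <- ifelse(table$boundary == "normal_overweight",
                       ifelse(table$direction == "up", 1, 2),
                       ifelse(table$direction == "up", 2, 3))
  ai <- match(table$age, curve$ages)
  table$origin_prev <- curve$P[cbind(ai, origin_cat)]
  table$pop_count <- pop$count[match(table$age, pop$age)]
  table$net_count <- table$net_prob * table$origin_prev * table$pop_count
  table$net_persons <- round(table$net_count)
  table
}
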