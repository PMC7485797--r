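#' Two-cause elimination: net probabilities of death from crude proportions
#'
#' Given the crude proportions `D1` and `D2` of a cohort observed dying of
#' two competing causes, solves for the net probabilities `(q1, q2)` of
#' dying from each cause if the other were eliminated, assuming independent
#' causes with proportional risks.  `q2` is the smaller root of the
#' quadratic
#' \deqn{D_1 q^2 - (D_1 + D_2)\, q + D_2 (D_1 + D_2) = 0,}
#' i.e. `a = D1`, `b = -(D1 + D2)`, `c = D2 (D1 + D2)`; the larger root
#' exceeds 1 whenever some of the cohort survives.  `q1` follows from joint
#' survival `(1 - q1)(1 - q2) = 1 - (D1 + D2)`.  The solution satisfies risk
#' proportionality `q1 / q2 = D1 / D2` when both proportions are positive.
#'
#' @param D1,D2 crude mortality proportions, each `>= 0`, with
#'   `D1 + D2 < 1` (some survivors are required for net probabilities to be
#'   defined).
#' @return named numeric vector `c(q1, q2)`, each in `[0, 1)`.
#' @examples
#' solve_two_cause(0.3, 0.3)    # symmetric: both 1 - sqrt(0.4)
#' solve_two_cause(0.5, 0)      # absent competitor leaves crude = net
#' solve_two_cause(0.701, 0.236)
#' @export
solve_two_cause <- function(D1, D2) {
  if (length(D1) != 1L || length(D2) != 1L) stop("D1 and D2 must be scalars")
  D1 <- unname(D1)
  D2 <- unname(D2)
  if (is.na(D1) || is.na(D2) || D1 < 0 || D2 < 0) {
    stop("crude proportions must be non-negative")
  }
  if (D1 + D2 >= 1) {
    stop("no survivors (D1 + D2 >= 1); net probabilities are undefined")
  }
  if (D1 == 0) return(c(q1 = 0, q2 = D2))
  if (D2 == 0) return(c(q1 = D1, q2 = 0))
  a <- D1
  b <- -(D1 + D2)
  cc <- D2 * (D1 + D2)
  disc <- b * b - 4 * a * cc
  if (disc < 0) disc <- 0  # guard: analytically non-negative on the domain
  q2 <- (-b - sqrt(disc)) / (2 * a)  # smaller root; the larger exceeds 1
  q1 <- 1 - (1 - (D1 + D2)) / (1 - q2)
  c(q1 = q1, q2 = q2)
}

#' Net probabilities of death for every cause of a mortality profile
#'
#' For each cause `i` this solves the two-cause elimination with the focal
#' cause against all remaining causes pooled (`D_i` versus
#' `sum(D[-i])`) and takes the focal net probability: the probability of
#' dying from cause `i` in the absence of every other cause.
#'
#' @param D named numeric vector of crude cause-specific mortality
#'   proportions `aD_i` (the [cause_totals()] of a life table); `sum(D)`
#'   must be `< 1`.
#' @return named numeric vector of net probabilities `q_i`.
#' @examples
#' net_probabilities(c(cannibalism = 0.3, other = 0.3))
#' @export
net_probabilities <- function(D) {
  D <- .as_profile(D)
  q <- vapply(seq_along(D), function(i) {
    unname(solve_two_cause(D[i], sum(D[-i]))["q1"])
  }, numeric(1))
  names(q) <- names(D)
  q
}

#' Joint mortality of independent causes
#'
#' The chance of dying from at least one of a set of independently acting
#' causes with net probabilities `q`: `1 - prod(1 - q)`.  The empty set
#' gives 0.
#'
#' @param q numeric vector of net probabilities, each in `[0, 1)`.
#' @return a proportion in `[0, 1)`.
#' @export
joint_mortality <- function(q) {
  if (length(q) == 0L) return(0)
  if (any(q < 0 | q >= 1)) stop("net probabilities must lie in [0, 1)")
  1 - prod(1 - q)
}

#' Crude combined mortality of a subset of causes
#'
#' The combined percentage of the original cohort killed by a subset of
#' causes with all causes operating: `100 * sum(D[subset])`, reported at
#' integer rounding as in combination statements ("these three causes would
#' kill X% of the population").
#'
#' @param D named crude mortality profile (see [net_probabilities()]).
#' @param subset character vector of cause names (or integer indices) to
#'   combine; must be non-empty.
#' @return the combined percentage, rounded to the nearest integer.
#' @examples
#' D <- c(parasitism = 0.015, plant_defense = 0.165, cannibalism = 0.701,
#'        unknown = 0.054, pathogens = 0.002)
#' crude_combination(D, c("cannibalism", "unknown", "plant_defense"))
#' @export
crude_combination <- function(D, subset) {
  D <- .as_profile(D, require_survivors = FALSE)
  if (length(subset) == 0L) stop("subset of causes must be non-empty")
  if (is.character(subset)) {
    bad <- setdiff(subset, names(D))
    if (length(bad) > 0L) stop("unknown cause(s): ", paste(bad, collapse = ", "))
  }
  # report-style rounding: halves away from zero, not banker's rounding
  floor(100 * sum(D[subset]) + 0.5)
}

#' Irreplaceable mortality of a focal cause
#'
#' The part of total mortality that would not be replaced by the remaining
#' causes if the focal cause were removed: total mortality with all causes
#' operating minus the mortality the remaining causes would inflict on
#' their own.  The latter is the net probability of the pooled non-focal
#' complement from the focal-versus-rest two-cause solve (the `q2`
#' companion of the focal cause's net probability), which keeps the result
#' within `[0, D_focal]`: the complement's net mortality always lies
#' between `sum(D) - D_focal` and `sum(D)`.  The result is floored at zero
#' against floating-point negatives.
#'
#' In `"totals"` mode the elimination operates on whole-cohort crude totals
#' `aD_i`.  In `"per_stage"` mode (requires an [mdlt()] object) the focal
#' cause is eliminated within each stage's conditional probabilities,
#' survival is recombined across stages, and the subtraction happens on the
#' recombined total.
#'
#' @param x a named crude mortality profile, or an `mdlt` object.
#' @param focal cause name (or index) whose irreplaceable mortality is
#'   wanted.
#' @param mode `"totals"` or `"per_stage"`.
#' @return a proportion in `[0, D_focal]`.
#' @examples
#' D <- c(parasitism = 0.015, plant_defense = 0.165, cannibalism = 0.701,
#'        unknown = 0.054, pathogens = 0.002)
#' irreplaceable(D, "cannibalism")
#' @export
irreplaceable <- function(x, focal, mode = c("totals", "per_stage")) {
  mode <- match.arg(mode)
  if (inherits(x, "mdlt")) {
    if (mode == "per_stage") return(.irreplaceable_per_stage(x, focal))
    D <- cause_totals(x)
  } else {
    if (mode == "per_stage") {
      stop("per_stage mode requires an 'mdlt' object with stage-level counts")
    }
    D <- .as_profile(x)
  }
  D <- .as_profile(D)
  focal <- .focal_name(D, focal)
  q_rest <- unname(solve_two_cause(D[focal], sum(D) - D[focal])["q2"])
  max(0, sum(D) - q_rest)
}

# elimination within each stage's conditional probabilities, survival
# recombined across stages before the subtraction
.irreplaceable_per_stage <- function(x, focal) {
  cq <- x$conditional
  focal <- .focal_name(stats::setNames(numeric(ncol(cq)), colnames(cq)), focal)
  surv_wo <- 1
  for (s in seq_len(nrow(cq))) {
    prof <- cq[s, ]
    if (sum(prof) >= 1) {
      stop("stage ", rownames(cq)[s],
           " has no survivors; per-stage elimination undefined")
    }
    if (sum(prof) == 0) next
    q_rest <- unname(solve_two_cause(prof[focal], sum(prof) - prof[focal])["q2"])
    surv_wo <- surv_wo * (1 - q_rest)
  }
  max(0, x$total_mortality - (1 - surv_wo))
}

#' Elimination-of-cause analysis of a life table
#'
#' Runs the full elimination analysis on a fitted life table (or a crude
#' mortality profile): net probability of death for each cause in the
#' absence of the others, and each cause's irreplaceable mortality.
#'
#' @param x an `mdlt` object or a named crude mortality profile.
#' @param mode `"totals"` (default; elimination on whole-cohort crude
#'   totals) or `"per_stage"` (within-stage elimination, survival recombined
#'   across stages; requires an `mdlt` object).
#' @param ... unused.
#' @return an object of class `mdlt_elim`: a data.frame-backed summary with
#'   columns `cause`, `D` (crude), `q` (net), `irreplaceable`, plus
#'   attributes `mode`, `total_mortality`, `survival`.
#' @examples
#' D <- c(parasitism = 0.015, plant_defense = 0.165, cannibalism = 0.701,
#'        unknown = 0.054, pathogens = 0.002)
#' eliminate(D)
#' @export
eliminate <- function(x, ...) UseMethod("eliminate")

#' @rdname eliminate
#' @export
eliminate.mdlt <- function(x, mode = c("totals", "per_stage"), ...) {
  mode <- match.arg(mode)
  D <- cause_totals(x)
  out <- .eliminate_profile(D, mode = mode, table = x)
  attr(out, "stratum") <- x$stratum
  out
}

#' @rdname eliminate
#' @export
eliminate.default <- function(x, mode = "totals", ...) {
  mode <- match.arg(mode, c("totals", "per_stage"))
  if (mode == "per_stage") {
    stop("per_stage mode requires an 'mdlt' object with stage-level counts")
  }
  .eliminate_profile(.as_profile(x), mode = "totals", table = NULL)
}

.eliminate_profile <- function(D, mode, table = NULL) {
  q <- net_probabilities(D)
  if (mode == "per_stage") {
    # net probability per cause recombined across stages
    cq <- table$conditional
    q <- vapply(colnames(cq), function(cs) {
      s_i <- 1
      for (s in seq_len(nrow(cq))) {
        prof <- cq[s, ]
        if (sum(prof) == 0) next
        q_stage <- net_probabilities(prof)
        s_i <- s_i * (1 - q_stage[cs])
      }
      1 - unname(s_i)
    }, numeric(1))
    irr <- vapply(names(D), function(cs) .irreplaceable_per_stage(table, cs),
                  numeric(1))
  } else {
    irr <- vapply(names(D), function(cs) {
      q_rest <- unname(solve_two_cause(D[cs], sum(D) - D[cs])["q2"])
      max(0, sum(D) - q_rest)
    }, numeric(1))
  }
  structure(
    data.frame(cause = names(D), D = unname(D), q = unname(q),
               irreplaceable = unname(irr), stringsAsFactors = FALSE),
    mode = mode,
    total_mortality = sum(D),
    survival = 1 - sum(D),
    class = c("mdlt_elim", "data.frame")
  )
}

#' @export
print.mdlt_elim <- function(x, ...) {
  cat("Elimination-of-cause analysis (mode: ", attr(x, "mode"), ")\n", sep = "")
  if (!is.null(attr(x, "stratum"))) {
    cat("Stratum: ", attr(x, "stratum"), "\n", sep = "")
  }
  cat("\n")
  df <- as.data.frame(x)
  df$D <- .round_display(df$D)
  df$q <- .round_display(df$q)
  df$irreplaceable <- .round_display(df$irreplaceable)
  print(df, row.names = FALSE)
  cat("\nTotal mortality: ", .round_display(attr(x, "total_mortality")),
      "   Survival: ", .round_display(attr(x, "survival")), "\n", sep = "")
  invisible(x)
}

#' Crude and net mortality of cause subsets
#'
#' For each subset of causes, reports the crude combined percentage
#' (`100 * sum(D)` at integer rounding) and the joint net mortality
#' `1 - prod(1 - q)` of the subset's net probabilities.
#'
#' @param x an `mdlt` object or named crude profile.
#' @param subsets a named list of character vectors of cause names.  The
#'   default enumerates each single cause and the full set.
#' @return data.frame with columns `subset`, `crude_pct`, `net_joint`.
#' @export
combination_table <- function(x, subsets = NULL) {
  D <- if (inherits(x, "mdlt")) cause_totals(x) else .as_profile(x)
  if (is.null(subsets)) {
    subsets <- c(as.list(names(D)), list(all = names(D)))
    names(subsets) <- c(names(D), "all")
  }
  q <- net_probabilities(D)
  data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    crude_pct = vapply(subsets, function(s) crude_combination(D, s), numeric(1)),
    net_joint = vapply(subsets, function(s) joint_mortality(q[s]), numeric(1)),
    row.names = names(subsets),
    stringsAsFactors = FALSE
  )
}

# validate and name a crude mortality profile
.as_profile <- function(D, require_survivors = TRUE) {
  D <- unlist(D)
  if (!is.numeric(D) || length(D) == 0L) stop("profile must be numeric")
  if (any(is.na(D) | D < 0)) stop("crude proportions must be non-negative")
  if (require_survivors && sum(D) >= 1) {
    stop("no survivors (sum(D) >= 1); net probabilities are undefined")
  }
  if (is.null(names(D)) || any(!nzchar(names(D)))) {
    if (length(D) == length(mortality_causes())) {
      names(D) <- mortality_causes()
    } else {
      names(D) <- paste0("cause_", seq_along(D))
    }
  }
  D
}

.focal_name <- function(D, focal) {
  if (is.numeric(focal)) focal <- names(D)[focal]
  if (!focal %in% names(D)) stop("unknown focal cause: ", focal)
  focal
}
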