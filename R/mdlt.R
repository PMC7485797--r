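#' Fit an abridged multiple decrement life table
#'
#' Builds a multiple decrement life table (MDLT) from stage-by-cause death
#' counts.  For each non-terminal stage the stage-specific probability of
#' dying from all causes is `aq_x = d_x / l_x`, where `l_x` is the number of
#' individuals examined at the stage and `d_x` the deaths among them.  The
#' cohort columns follow by recursion from a radix of 1: the proportion
#' dying in the stage is `ad_x = al_x * aq_x` and the proportion alive at
#' the next stage `al_{x+1} = al_x - ad_x`.  Stage mortality is apportioned
#' among causes proportionally to the observed cause-specific deaths,
#' `ad_ix = al_x * d_ix / l_x`, so the cause columns sum to `ad_x` exactly.
#'
#' Because stage counts come from independent cross-sectional samples, the
#' raw `l_x` column need not be monotone across stages; the cohort survival
#' column never uses raw `l_x` directly, only the `aq_x` recursion.
#'
#' @param counts a data.frame with columns `stage`, `l_x` and
#'   `d_parasitism`, `d_plant_defense`, `d_cannibalism`, `d_unknown`,
#'   `d_pathogens`, e.g. one stratum of [aggregate_counts()] output.  Rows
#'   sharing a stage (multiple strata) are summed, which is how a pooled
#'   table is built from stratified counts.
#' @param stratum label stored on the table (default `"pooled"`).
#' @param skip_empty_stages if a non-terminal stage has `l_x = 0`, bridge it
#'   with `aq_x = 0` and a warning instead of erroring.
#' @param digits optional rounding, in decimal places, applied to `al_x` and
#'   `ad_x` at every step of the recursion.  `NULL` (the default) keeps full
#'   precision; `3` reproduces desk arithmetic on a printed 3-decimal table.
#' @return an object of class `mdlt`: a list with elements `stratum`,
#'   `table` (stage rows with `l_x, d_x, aq_x, al_x, ad_x`), `decrements`
#'   (matrix of `ad_ix`, stage x cause), `conditional` (matrix of
#'   `cq_ix = d_ix / l_x`), `cause_totals`, `total_mortality`,
#'   `final_survival`.
#' @seealso [mdlt_from_aq()], [cause_totals()], [eliminate()]
#' @examples
#' counts <- data.frame(
#'   stage = c("egg", "larva_i", "larva_iii", "larva_iv", "larva_v"),
#'   l_x = c(100, 80, 60, 40, 30),
#'   d_parasitism = c(0, 0, 6, 1, 1),
#'   d_plant_defense = c(0, 20, 0, 0, 0),
#'   d_cannibalism = c(40, 5, 0, 0, 0),
#'   d_unknown = c(0, 0, 3, 2, 1),
#'   d_pathogens = c(0, 0, 0, 1, 1)
#' )
#' fit <- mdlt(counts)
#' coef(fit)
#' @export
mdlt <- function(counts, stratum = "pooled", skip_empty_stages = FALSE,
                 digits = NULL) {
  causes <- mortality_causes()
  dcols <- paste0("d_", causes)
  need <- c("stage", "l_x", dcols)
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0L) {
    stop("counts are missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(counts$stage), stage_levels())
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  # sum over any replicate rows per stage (pooling)
  counts <- stats::aggregate(counts[c("l_x", dcols)],
                             by = list(stage = counts$stage), FUN = sum)
  nonterm <- setdiff(stage_levels(), "adult")
  row <- match(nonterm, counts$stage)
  l <- ifelse(is.na(row), 0, counts$l_x[row])
  d_ix <- matrix(0, nrow = length(nonterm), ncol = length(causes),
                 dimnames = list(nonterm, causes))
  for (k in seq_along(causes)) {
    d_ix[, k] <- ifelse(is.na(row), 0, counts[[dcols[k]]][row])
  }
  d <- rowSums(d_ix)
  if (any(d_ix < 0)) stop("negative death counts")
  if (any(d > l)) stop("deaths exceed examined count at stage(s): ",
                       paste(nonterm[d > l], collapse = ", "))
  if (any(l == 0)) {
    if (!skip_empty_stages) {
      stop("no examined individuals at stage(s): ",
           paste(nonterm[l == 0], collapse = ", "),
           " (use skip_empty_stages = TRUE to bridge with aq_x = 0)")
    }
    warning("bridging empty stage(s) with aq_x = 0: ",
            paste(nonterm[l == 0], collapse = ", "))
  }
  if (any(d_ix[match(c("egg", "larva_i"), nonterm), "parasitism"] > 0)) {
    warning("parasitism deaths before the vulnerable window (Larva III)")
  }

  aq <- ifelse(l > 0, d / l, 0)
  cq_ix <- sweep(d_ix, 1, ifelse(l > 0, l, 1), "/")
  frac <- sweep(cq_ix, 1, ifelse(aq > 0, aq, 1), "/")  # cause shares of aq

  rec <- .mdlt_recursion(aq, digits = digits)
  ad_ix <- sweep(frac, 1, rec$ad, "*")

  structure(list(
    stratum = stratum,
    table = data.frame(
      stage = c(nonterm, "adult"),
      l_x = c(l, if (!is.na(match("adult", counts$stage)))
        counts$l_x[match("adult", counts$stage)] else NA_real_),
      d_x = c(d, NA_real_),
      aq_x = c(aq, NA_real_),
      al_x = rec$al,
      ad_x = c(rec$ad, NA_real_),
      stringsAsFactors = FALSE
    ),
    decrements = ad_ix,
    conditional = cq_ix,
    cause_totals = colSums(ad_ix),
    total_mortality = sum(rec$ad),
    final_survival = rec$al[length(rec$al)],
    digits = digits,
    call = match.call()
  ), class = "mdlt")
}

# survival recursion from stage probabilities of dying; optional per-step
# rounding mirrors desk arithmetic on a printed table
.mdlt_recursion <- function(aq, digits = NULL) {
  n <- length(aq)
  al <- numeric(n + 1L)
  ad <- numeric(n)
  al[1] <- 1
  for (x in seq_len(n)) {
    ad[x] <- al[x] * aq[x]
    if (!is.null(digits)) ad[x] <- round(ad[x], digits)
    al[x + 1L] <- al[x] - ad[x]
    if (!is.null(digits)) al[x + 1L] <- round(al[x + 1L], digits)
  }
  list(al = al, ad = ad)
}

#' Build a life table directly from stage probabilities of dying
#'
#' Constructs an `mdlt` object from the stage-specific probabilities of
#' dying `aq_x` (and optionally the printed per-stage cause decrements
#' `ad_ix`), as when re-deriving the cohort columns of a published table.
#'
#' @param aq numeric vector of stage probabilities of dying for the
#'   non-terminal stages, in stage order.
#' @param decrements optional matrix of unconditional per-stage cause
#'   decrements `ad_ix` (rows = the same stages, columns = the five causes
#'   in [mortality_causes()] order).  When omitted, stage mortality from the
#'   recursion is left unapportioned (all-zero decrements).
#' @param stages stage identifiers for the rows of `aq` (default: the five
#'   non-terminal stages).
#' @param digits per-step rounding of the recursion, as in [mdlt()].
#' @param stratum label stored on the table.
#' @return an object of class `mdlt`.
#' @examples
#' # desk-checking a printed table: survival to adult from its aq_x column
#' fit <- mdlt_from_aq(c(0.619, 0.478, 0.554, 0.169, 0.1368), digits = 3)
#' fit$final_survival
#' @export
mdlt_from_aq <- function(aq, decrements = NULL,
                         stages = setdiff(stage_levels(), "adult"),
                         digits = NULL, stratum = "pooled") {
  if (length(aq) != length(stages)) stop("aq and stages lengths differ")
  if (any(aq < 0 | aq >= 1 + 1e-12)) stop("aq_x must lie in [0, 1]")
  causes <- mortality_causes()
  rec <- .mdlt_recursion(aq, digits = digits)
  if (is.null(decrements)) {
    ad_ix <- matrix(0, nrow = length(stages), ncol = length(causes),
                    dimnames = list(stages, causes))
  } else {
    ad_ix <- as.matrix(decrements)
    if (nrow(ad_ix) != length(stages) || ncol(ad_ix) != length(causes)) {
      stop("decrements must be a ", length(stages), " x ", length(causes),
           " matrix (stages x causes)")
    }
    dimnames(ad_ix) <- list(stages, causes)
  }
  cq_ix <- sweep(ad_ix, 1, ifelse(rec$al[-length(rec$al)] > 0,
                                  rec$al[-length(rec$al)], 1), "/")
  structure(list(
    stratum = stratum,
    table = data.frame(
      stage = c(stages, "adult"),
      l_x = NA_real_,
      d_x = NA_real_,
      aq_x = c(aq, NA_real_),
      al_x = rec$al,
      ad_x = c(rec$ad, NA_real_),
      stringsAsFactors = FALSE
    ),
    decrements = ad_ix,
    conditional = cq_ix,
    cause_totals = colSums(ad_ix),
    total_mortality = sum(rec$ad),
    final_survival = rec$al[length(rec$al)],
    digits = digits,
    call = match.call()
  ), class = "mdlt")
}

#' Cause totals of a multiple decrement life table
#'
#' Sums the unconditional per-stage cause decrements `ad_ix` over stages,
#' giving the crude probability `aD_i` that a member of the original cohort
#' dies of cause `i` with all causes operating.
#'
#' @param x an `mdlt` object, or a stage-by-cause matrix of `ad_ix` values.
#' @return named numeric vector of `aD_i`, in cause order.
#' @export
cause_totals <- function(x) {
  if (inherits(x, "mdlt")) return(colSums(x$decrements))
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- mortality_causes()[seq_len(ncol(m))]
  colSums(m)
}

#' @rdname cause_totals
#' @param object,... method arguments; `coef()` on an `mdlt` returns its
#'   cause totals.
#' @export
coef.mdlt <- function(object, ...) cause_totals(object)

#' Percentage mortality in the presence of all causes
#'
#' @param x an `mdlt` object.
#' @return named vector `100 * aD_i`: crude cause-specific mortality of the
#'   original cohort with every cause operating.
#' @export
pct_in_presence <- function(x) 100 * cause_totals(x)

# display rounding used in printed tables: 3 decimals, 4 for small nonzero
# entries so values like 0.0007 stay visible
.round_display <- function(v) {
  ifelse(!is.na(v) & v != 0 & abs(v) < 0.01, round(v, 4), round(v, 3))
}

#' @export
print.mdlt <- function(x, ...) {
  cat("Multiple decrement life table (stratum: ", x$stratum, ")\n\n", sep = "")
  tab <- as.data.frame(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], .round_display)
  print(tab, row.names = FALSE)
  cat("\nTotal mortality: ", .round_display(x$total_mortality),
      "   Final survival: ", .round_display(x$final_survival), "\n", sep = "")
  invisible(x)
}

#' Flatten a life table to a data frame
#'
#' One row per stage, with the cohort columns and the per-stage cause
#' decrements (`ad_ix`) as `aq_1x ... aq_5x` in cause order, matching the
#' column layout of a printed MDLT.  The terminal adult row repeats the
#' final survival in the `ad_x` column, the layout convention of printed
#' tables where the adult row closes the accounting to 1.
#'
#' @param x an `mdlt` object.
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.mdlt <- function(x, row.names = NULL, optional = FALSE, ...) {
  tab <- x$table
  dec <- rbind(x$decrements, adult = rep(NA_real_, ncol(x$decrements)))
  colnames(dec) <- paste0("aq_", seq_len(ncol(dec)), "x")
  out <- cbind(tab, as.data.frame(dec))
  out$ad_x[out$stage == "adult"] <- x$final_survival
  out$stage <- stage_labels(out$stage)
  rownames(out) <- NULL
  out
}

#' @export
summary.mdlt <- function(object, ...) {
  structure(list(
    stratum = object$stratum,
    table = as.data.frame(object),
    cause_totals = cause_totals(object),
    pct_in_presence = pct_in_presence(object),
    total_mortality = object$total_mortality,
    final_survival = object$final_survival
  ), class = "summary.mdlt")
}

#' @export
print.summary.mdlt <- function(x, ...) {
  cat("Multiple decrement life table (stratum: ", x$stratum, ")\n\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], .round_display)
  print(tab, row.names = FALSE)
  cat("\nCrude mortality in the presence of all causes (% of cohort):\n")
  print(round(x$pct_in_presence, 1))
  cat("\nTotal mortality: ", .round_display(x$total_mortality),
      "   Final survival: ", .round_display(x$final_survival), "\n", sep = "")
  invisible(x)
}

#' @export
plot.mdlt <- function(x, ...) {
  dec <- t(x$decrements)
  colnames(dec) <- stage_labels(colnames(x$decrements))
  graphics::barplot(dec, legend.text = rownames(dec),
                    ylab = "proportion of original cohort dying",
                    xlab = "stage",
                    args.legend = list(x = "topright", bty = "n"), ...)
  invisible(x)
}

#' Serialize a life table in the printed-table CSV layout
#'
#' Writes one row per stage plus a Total row, with display rounding (3
#' decimals; 4 for nonzero entries below 0.01).  Column headers follow the
#' printed layout: `Category`, `l_x`, `aq_x`, `al_x`, `ad_x`, then one
#' decrement column per cause.
#'
#' @param x an `mdlt` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mdlt <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .round_display)
  names(df) <- c("Category", "l_x", "d_x", "aq_x", "al_x", "ad_x",
                 paste0("aq_", seq_along(mortality_causes()), "x_",
                        mortality_causes()))
  total <- df[1, ]
  total[1, ] <- NA
  total$Category <- "Total"
  total$ad_x <- .round_display(x$total_mortality + x$final_survival)
  tot <- .round_display(cause_totals(x))
  for (k in seq_along(tot)) total[[6 + k]] <- tot[k]
  utils::write.csv(rbind(df, total), path, row.names = FALSE, na = "")
  invisible(path)
}
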