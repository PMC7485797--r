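#' Read dissection records from CSV
#'
#' A dissection-records file has one row per dissected stem or stub, with the
#' columns `site, year, cultivar, block, plot, sample_kind, week, stub_phase,
#' unit_id, n_eggs, n_live_larvae, dead_evidence, emerged`.  The
#' `dead_evidence` cell holds one semicolon-separated group of evidence codes
#' per dead occupant, comma-separated within a group, e.g.
#' `"DEAD_NEONATE,FEEDING_SCAR_ONLY;MULTIPLE_LARVAE"`.
#'
#' Rows violating the record invariants (a stem sample without a week, a stub
#' sample with one, negative counts, unknown evidence codes, `emerged` set
#' outside post-flight stubs) are rejected and reported row-indexed in the
#' `diagnostics` attribute of the result; with `strict = TRUE` any rejected
#' row is an error instead.
#'
#' @param path file path of the records CSV.
#' @param strict error on malformed rows instead of dropping them.
#' @return a `data.frame` of validated records (class `dissection_records`)
#'   with attribute `diagnostics`, a data.frame of `(row, message)` for
#'   rejected rows.
#' @seealso [write_records()], [aggregate_counts()]
#' @export
read_records <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  required <- c("site", "year", "cultivar", "block", "plot", "sample_kind",
                "week", "stub_phase", "unit_id", "n_eggs", "n_live_larvae",
                "dead_evidence", "emerged")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("records file is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_records(raw, strict = strict)
}

#' Validate raw dissection records
#'
#' @param x a data.frame with the records columns as character vectors.
#' @param strict error on malformed rows instead of dropping them.
#' @return as [read_records()].
#' @export
validate_records <- function(x, strict = FALSE) {
  n <- nrow(x)
  year <- suppressWarnings(as.integer(x$year))
  week <- suppressWarnings(as.integer(as.character(x$week)))
  n_eggs <- suppressWarnings(as.integer(x$n_eggs))
  n_live <- suppressWarnings(as.integer(x$n_live_larvae))
  emerged <- tolower(trimws(as.character(x$emerged))) %in% c("true", "t", "1", "yes")
  stub_phase <- trimws(as.character(x$stub_phase))
  stub_phase[is.na(stub_phase) | stub_phase == ""] <- NA_character_
  kind <- trimws(as.character(x$sample_kind))
  evidence <- as.character(x$dead_evidence)
  evidence[is.na(evidence)] <- ""

  msgs <- vector("list", n)
  add <- function(i, m) msgs[[i]] <<- c(msgs[[i]], m)

  for (i in seq_len(n)) {
    if (!kind[i] %in% c("stem", "stub")) {
      add(i, sprintf("sample_kind '%s' is not 'stem' or 'stub'", kind[i]))
      next
    }
    if (kind[i] == "stem") {
      if (is.na(week[i]) || week[i] < 1L || week[i] > 9L) {
        add(i, "stem sample requires a week in 1-9")
      }
      if (!is.na(stub_phase[i])) add(i, "stem sample must not carry a stub_phase")
      if (emerged[i]) add(i, "emerged is only valid for post-flight stubs")
    } else {
      if (!is.na(week[i])) add(i, "stub sample must not carry a week")
      if (is.na(stub_phase[i]) ||
          !stub_phase[i] %in% c("pre_flight", "post_flight")) {
        add(i, "stub sample requires stub_phase 'pre_flight' or 'post_flight'")
      } else if (emerged[i] && stub_phase[i] != "post_flight") {
        add(i, "emerged is only valid for post-flight stubs")
      }
    }
    if (is.na(n_eggs[i]) || n_eggs[i] < 0L) add(i, "n_eggs must be a count >= 0")
    if (is.na(n_live[i]) || n_live[i] < 0L) add(i, "n_live_larvae must be a count >= 0")
    err <- tryCatch({ parse_evidence(evidence[i]); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) add(i, err)
  }

  bad <- which(vapply(msgs, length, integer(1)) > 0L)
  diagnostics <- data.frame(
    row = rep(bad, vapply(msgs[bad], length, integer(1))),
    message = unlist(msgs[bad], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(diagnostics) == 0L) {
    diagnostics <- data.frame(row = integer(), message = character(),
                              stringsAsFactors = FALSE)
  }
  if (strict && nrow(diagnostics) > 0L) {
    stop("malformed record row(s): ",
         paste(sprintf("row %d: %s", diagnostics$row, diagnostics$message),
               collapse = "; "))
  }

  keep <- setdiff(seq_len(n), bad)
  out <- data.frame(
    site = trimws(as.character(x$site))[keep],
    year = year[keep],
    cultivar = trimws(as.character(x$cultivar))[keep],
    block = trimws(as.character(x$block))[keep],
    plot = trimws(as.character(x$plot))[keep],
    sample_kind = kind[keep],
    week = week[keep],
    stub_phase = stub_phase[keep],
    unit_id = trimws(as.character(x$unit_id))[keep],
    n_eggs = n_eggs[keep],
    n_live_larvae = n_live[keep],
    dead_evidence = trimws(evidence)[keep],
    emerged = emerged[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("dissection_records", "data.frame")
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Parse a dead-evidence cell
#'
#' @param x a single `dead_evidence` string: semicolon-separated occupant
#'   groups, comma-separated codes within a group.  An empty string means no
#'   dead occupants.
#' @return a list with one character vector of evidence codes per dead
#'   occupant.
#' @export
parse_evidence <- function(x) {
  x <- trimws(as.character(x))
  if (length(x) != 1L) stop("parse_evidence expects a single string")
  if (is.na(x) || !nzchar(x)) return(list())
  groups <- strsplit(x, ";", fixed = TRUE)[[1]]
  lapply(groups, function(g) {
    codes <- trimws(strsplit(g, ",", fixed = TRUE)[[1]])
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0L) stop("empty evidence group in '", x, "'")
    bad <- setdiff(codes, evidence_codes())
    if (length(bad) > 0L) {
      stop("unknown evidence code(s): ", paste(bad, collapse = ", "))
    }
    codes
  })
}

#' Write dissection records to CSV
#'
#' Inverse of [read_records()]; the written file round-trips field-by-field.
#'
#' @param records a records data.frame as returned by [read_records()] or
#'   [simulate_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- as.data.frame(records)
  out$emerged <- ifelse(out$emerged, "true", "false")
  out$week <- ifelse(is.na(out$week), "", as.character(out$week))
  out$stub_phase <- ifelse(is.na(out$stub_phase), "", out$stub_phase)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate dissection records into stage-by-cause counts
#'
#' For each stratum and developmental stage this tallies `l_x`, the number of
#' occupants observed at that stage (alive there plus dead there), and
#' `d_<cause>`, the dead occupants classified to each cause.  Dead occupants
#' are staged by [assign_stage()] from the sampling occasion; occupants whose
#' evidence is purely egg-multiplicity (`MULTIPLE_EGGS`, `LARVA_PLUS_EGG`)
#' are staged as eggs.  An emerged post-flight stub counts one occupant alive
#' through Larva V and observed as an adult.
#'
#' With `prospective = TRUE` (the field scoring convention) surplus live
#' occupants of a multiply-occupied stem are scored as doomed to obligate
#' cannibalism at dissection time: when a live larva is present, every live
#' egg is a cannibalism decrement at the egg stage and every live larva
#' beyond the first a cannibalism decrement at its observed larval stage; in
#' an all-egg stem with `e > 1` eggs, `e - 1` are egg-stage cannibalism
#' decrements.  A doomed occupant still counts only once in `l_x`.  Disable
#' prospective scoring for records that already carry explicit cannibalism
#' evidence for every such death (e.g. census output of [simulate_cohort()]),
#' as scoring both would double-count.
#'
#' @param records validated records.
#' @param by character vector of stratum columns (subset of
#'   `site, year, cultivar, block, plot`), or `NULL` to pool everything into
#'   a single `"pooled"` stratum.
#' @param prospective apply the surplus-occupancy cannibalism scoring rule.
#' @return a data.frame with the `by` columns (or `stratum = "pooled"`) and
#'   columns `stage`, `l_x`, `d_parasitism`, `d_plant_defense`,
#'   `d_cannibalism`, `d_unknown`, `d_pathogens`: one row per stratum and
#'   stage in canonical order, zero rows included.
#' @export
aggregate_counts <- function(records, by = NULL, prospective = TRUE) {
  causes <- mortality_causes()
  stages <- stage_levels()
  dcols <- paste0("d_", causes)
  records <- as.data.frame(records)
  n <- nrow(records)

  if (is.null(by)) {
    strat <- rep("pooled", n)
  } else {
    bad <- setdiff(by, c("site", "year", "cultivar", "block", "plot"))
    if (length(bad) > 0L) stop("unknown stratum column(s): ", paste(bad, collapse = ", "))
    strat <- do.call(paste, c(lapply(records[by], as.character), sep = "\r"))
  }
  strata <- unique(strat)

  out <- expand.grid(stage = stages, stratum = strata,
                     stringsAsFactors = FALSE)[, c("stratum", "stage")]
  out$alive <- rep(0, nrow(out))
  for (cc in dcols) out[[cc]] <- rep(0, nrow(out))
  # larval-stage prospective dooms land in d_cannibalism too
  out$doomed_l <- rep(0, nrow(out))
  cell <- function(s, stg) match(paste(s, stg), paste(out$stratum, out$stage))
  add <- function(s, stg, col, amount) {
    i <- cell(s, stg)
    v <- rowsum(amount, i)
    out[[col]][as.integer(rownames(v))] <<- out[[col]][as.integer(rownames(v))] + v[, 1]
  }

  if (n > 0L) {
    kind <- records$sample_kind
    week <- records$week
    phase <- records$stub_phase
    n_eggs <- records$n_eggs
    n_live <- records$n_live_larvae
    emerged <- records$emerged

    # stage of a larval occupant in each record (same mapping as assign_stage)
    lv_stage <- ifelse(kind == "stem",
                       ifelse(week <= 4L, "larva_i", "larva_iii"),
                       ifelse(phase == "pre_flight", "larva_iv", "larva_v"))
    if (any(kind == "stem" & week == 1L & n_live > 0L, na.rm = TRUE)) {
      warning("live larvae observed in week-1 stem samples; assigned Larva I")
    }

    # live occupants
    if (any(n_eggs > 0L)) add(strat, "egg", "alive", n_eggs)
    i <- which(n_live > 0L)
    if (length(i) > 0L) add(strat[i], lv_stage[i], "alive", n_live[i])
    i <- which(emerged)
    if (length(i) > 0L) {
      add(strat[i], "larva_v", "alive", rep(1, length(i)))
      add(strat[i], "adult", "alive", rep(1, length(i)))
    }

    # recorded dead occupants (one evidence group each)
    ev <- as.character(records$dead_evidence)
    ev[is.na(ev)] <- ""
    groups <- strsplit(ev, ";", fixed = TRUE)
    groups[!nzchar(ev)] <- list(character(0))
    occ_rec <- rep(seq_len(n), lengths(groups))
    if (length(occ_rec) > 0L) {
      codes <- lapply(unlist(groups, use.names = FALSE), function(g) {
        cs <- trimws(strsplit(g, ",", fixed = TRUE)[[1]])
        cs[nzchar(cs)]
      })
      cause <- classify_cause(codes)
      role_egg <- vapply(codes, function(g) all(g %in% .egg_evidence), logical(1))
      stg <- ifelse(role_egg, "egg", lv_stage[occ_rec])
      for (cs in unique(cause)) {
        i <- which(cause == cs)
        add(strat[occ_rec[i]], stg[i], paste0("d_", cs), rep(1, length(i)))
      }
    }

    # prospective cannibalism scoring of surplus live occupants; doomed
    # occupants are already counted in 'alive', so they enter the dead tally
    # without adding to l_x a second time
    if (prospective) {
      live <- n_eggs + n_live
      doomed_egg <- ifelse(live > 1L,
                           ifelse(n_live >= 1L, n_eggs, n_eggs - 1L), 0L)
      doomed_lv <- ifelse(live > 1L & n_live > 1L, n_live - 1L, 0L)
      i <- which(doomed_egg > 0L)
      if (length(i) > 0L) add(strat[i], "egg", "doomed_l", doomed_egg[i])
      i <- which(doomed_lv > 0L)
      if (length(i) > 0L) add(strat[i], lv_stage[i], "doomed_l", doomed_lv[i])
    }
  }

  out$l_x <- out$alive + rowSums(out[dcols])
  out$d_cannibalism <- out$d_cannibalism + out$doomed_l
  out$alive <- NULL
  out$doomed_l <- NULL

  if (!is.null(by)) {
    keyparts <- matrix(unlist(strsplit(out$stratum, "\r", fixed = TRUE)),
                       ncol = length(by), byrow = TRUE)
    for (k in seq_along(by)) out[[by[k]]] <- keyparts[, k]
    out$stratum <- NULL
  }
  out <- out[c(if (is.null(by)) "stratum" else by, "stage", "l_x", dcols)]
  rownames(out) <- NULL
  if (any(out$stage %in% c("egg", "larva_i") & out$d_parasitism > 0)) {
    warning("parasitism deaths recorded before the vulnerable window ",
            "(Larva III); check evidence coding")
  }
  out
}
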