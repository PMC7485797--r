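#' Mortality causes, evidence codes, and developmental stages
#'
#' The five mutually exclusive causes of death, in the fixed column order
#' used throughout the package: parasitism, plant defense, cannibalism,
#' unknown factors, pathogens.  Evidence codes are the physical observations
#' a dissector records for a dead occupant; each maps to exactly one cause
#' under [classify_cause()].  Stages are the sampled developmental classes of
#' the sawfly within a stem, ordered from egg to adult; the adult stage is
#' terminal and absorbs no decrements.
#'
#' @return `mortality_causes()`, `evidence_codes()` and `stage_levels()`
#'   return character vectors of the valid identifiers, in canonical order.
#' @export
mortality_causes <- function() {
  c("parasitism", "plant_defense", "cannibalism", "unknown", "pathogens")
}

#' @rdname mortality_causes
#' @export
evidence_codes <- function() {
  c(
    "MULTIPLE_EGGS", "LARVA_PLUS_EGG", "MULTIPLE_LARVAE",
    "DEAD_NEONATE", "FEEDING_SCAR_ONLY", "TINY_FRASS_FRAGMENT",
    "PARASITOID_LARVA", "PARASITOID_COCOON", "PARASITOID_EXIT_HOLE",
    "PREDATOR_LARVA",
    "WHITE_PINK_HYPHAE", "PINK_CADAVER",
    "DEAD_MULTI_INTERNODE"
  )
}

#' @rdname mortality_causes
#' @export
stage_levels <- function() {
  c("egg", "larva_i", "larva_iii", "larva_iv", "larva_v", "adult")
}

#' Human-readable stage labels
#'
#' @param stage character vector of stage identifiers.
#' @return character vector of display labels ("Egg", "Larva I", ...).
#' @export
stage_labels <- function(stage = stage_levels()) {
  map <- c(
    egg = "Egg", larva_i = "Larva I", larva_iii = "Larva III",
    larva_iv = "Larva IV", larva_v = "Larva V", adult = "Adult"
  )
  unname(map[stage])
}

# evidence -> cause lookup; precedence is handled in classify_cause
.evidence_cause <- c(
  MULTIPLE_EGGS        = "cannibalism",
  LARVA_PLUS_EGG       = "cannibalism",
  MULTIPLE_LARVAE      = "cannibalism",
  DEAD_NEONATE         = "plant_defense",
  FEEDING_SCAR_ONLY    = "plant_defense",
  TINY_FRASS_FRAGMENT  = "plant_defense",
  PARASITOID_LARVA     = "parasitism",
  PARASITOID_COCOON    = "parasitism",
  PARASITOID_EXIT_HOLE = "parasitism",
  PREDATOR_LARVA       = "parasitism",
  WHITE_PINK_HYPHAE    = "pathogens",
  PINK_CADAVER         = "pathogens",
  DEAD_MULTI_INTERNODE = "unknown"
)

# codes whose presence marks the dead occupant as an egg rather than a larva
.egg_evidence <- c("MULTIPLE_EGGS", "LARVA_PLUS_EGG")

#' Classify a dead occupant's evidence to a mortality cause
#'
#' Maps the set of evidence codes recorded for one dead occupant to a single
#' cause of death.  When codes pointing at different causes co-occur, a fixed
#' precedence applies: parasitism over pathogens over cannibalism over plant
#' defense over unknown.  Specific physical evidence (a parasitoid cocoon,
#' fungal hyphae) dominates circumstantial evidence such as multiple
#' occupancy.
#'
#' @param evidence a character vector of evidence codes for one occupant, or
#'   a list of such vectors.
#' @return a character scalar (or vector, for list input) drawn from
#'   [mortality_causes()].
#' @examples
#' classify_cause("MULTIPLE_LARVAE")
#' classify_cause(c("DEAD_NEONATE", "FEEDING_SCAR_ONLY"))
#' classify_cause(list(c("PREDATOR_LARVA"), c("WHITE_PINK_HYPHAE")))
#' @export
classify_cause <- function(evidence) {
  if (is.list(evidence)) {
    return(vapply(evidence, classify_cause, character(1)))
  }
  evidence <- as.character(evidence)
  if (length(evidence) == 0L || all(!nzchar(evidence))) {
    stop("empty evidence set: a dead occupant must carry at least one evidence code")
  }
  unknown <- setdiff(evidence, names(.evidence_cause))
  if (length(unknown) > 0L) {
    stop("unknown evidence code(s): ", paste(unknown, collapse = ", "))
  }
  causes <- .evidence_cause[evidence]
  # precedence order (strongest first)
  for (cause in c("parasitism", "pathogens", "cannibalism", "plant_defense", "unknown")) {
    if (cause %in% causes) return(cause)
  }
  stop("unreachable")
}

#' Assign a developmental stage to an observed occupant
#'
#' Stages are assigned from the sampling occasion and the occupant's role.
#' Egg occupants are always at the egg stage.  Larvae in weekly stem samples
#' are split by the parasitism window: weeks 2-4 precede parasitoid
#' vulnerability (Larva I) and weeks 5-9 fall within it (Larva III).
#' Overwintered larvae in stub collections are Larva IV (pre-flight) or
#' Larva V (post-flight); an emerged post-flight stub marks an adult.
#'
#' Week-1 larvae are biologically unexpected (week 1 carries eggs only) and
#' are assigned Larva I with a warning.
#'
#' @param sample_kind "stem" or "stub" (vectorised).
#' @param role "egg" or "larva" per occupant.
#' @param week sampling week (1-9) for stem samples; `NA` for stubs.
#' @param stub_phase "pre_flight" or "post_flight" for stubs; `NA` for stems.
#' @param emerged logical; `TRUE` only for post-flight stubs whose occupant
#'   emerged as an adult.
#' @return character vector of stage identifiers (see [stage_levels()]).
#' @examples
#' assign_stage("stem", "larva", week = 3)
#' assign_stage("stem", "larva", week = 7)
#' assign_stage("stub", "larva", stub_phase = "post_flight", emerged = TRUE)
#' @export
assign_stage <- function(sample_kind, role, week = NA_integer_,
                         stub_phase = NA_character_, emerged = FALSE) {
  n <- max(length(sample_kind), length(role), length(week),
           length(stub_phase), length(emerged))
  sample_kind <- rep_len(as.character(sample_kind), n)
  role <- rep_len(as.character(role), n)
  week <- rep_len(as.integer(week), n)
  stub_phase <- rep_len(as.character(stub_phase), n)
  emerged <- rep_len(as.logical(emerged), n)

  out <- character(n)
  is_egg <- role == "egg"
  out[is_egg] <- "egg"

  lv <- !is_egg
  stem <- lv & sample_kind == "stem"
  stub <- lv & sample_kind == "stub"

  if (any(stem & (is.na(week) | week < 1L | week > 9L))) {
    stop("stem-sample larvae require a sampling week in 1-9")
  }
  if (any(stem & week == 1L)) {
    warning("larva observed in a week-1 stem sample; assigned Larva I ",
            "(week 1 is expected to contain eggs only)")
  }
  out[stem & week <= 4L] <- "larva_i"
  out[stem & week >= 5L] <- "larva_iii"

  if (any(stub & !stub_phase %in% c("pre_flight", "post_flight"))) {
    stop("stub-sample occupants require stub_phase 'pre_flight' or 'post_flight'")
  }
  out[stub & stub_phase == "pre_flight"] <- "larva_iv"
  out[stub & stub_phase == "post_flight"] <- "larva_v"
  out[stub & emerged] <- "adult"
  out
}
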