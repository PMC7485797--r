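#' Default cultivar parameter set
#'
#' Eight barley cultivars spanning the attractiveness-versus-antibiosis
#' tradeoff: cultivars attractive to ovipositing females carry a higher mean
#' egg load per stem (driving obligate cannibalism) and weaker neonate
#' plant-defense mortality, and vice versa.  Values are chosen as a
#' realistic operating point for estimator validation, not as a calibration
#' to any particular field season.
#'
#' @return named list of per-cultivar parameter lists with elements
#'   `egg_intensity` (mean eggs per stem), `p_plant_defense` (per-neonate
#'   death probability at emergence), `p_parasitism` (per-larva probability
#'   in the vulnerable window), `p_unknown_early`, `p_pathogens`,
#'   `p_unknown_late` (stage-conditional probabilities for the late larval
#'   and overwintering stages).
#' @export
default_cultivars <- function() {
  mk <- function(intensity, pd) {
    list(egg_intensity = intensity, p_plant_defense = pd,
         p_parasitism = 0.06, p_unknown_early = 0.15,
         p_pathogens = 0.015, p_unknown_late = 0.08)
  }
  list(
    Celebration = mk(0.8, 0.65),
    Champion    = mk(0.8, 0.60),
    Craft       = mk(0.6, 0.75),
    Haxby       = mk(1.2, 0.50),
    Haybet      = mk(1.5, 0.45),
    Hockett     = mk(2.2, 0.25),
    Lavina      = mk(1.3, 0.50),
    Tradition   = mk(1.0, 0.55)
  )
}

#' Build and validate a cohort simulation configuration
#'
#' The defaults reproduce the replicated field design: three site-years,
#' three blocks per site-year, one plot per cultivar per block, weekly stem
#' samples of 3 bags x 35 stems per plot over 9 weeks, and 25-stub
#' collections before and after the adult flight period.
#'
#' @param n_sites number of site-years (1-3 with the default labels).
#' @param n_blocks blocks per site-year.
#' @param cultivars named list of per-cultivar parameters (see
#'   [default_cultivars()]); one plot per cultivar per block.
#' @param stems_per_plot number of stems in a plot's stand.
#' @param weeks number of weekly stem-sampling occasions.
#' @param bags_per_plot,stems_per_bag weekly sample size per plot is
#'   `bags_per_plot * stems_per_bag`.
#' @param stubs_per_collection stubs dissected per plot in each of the
#'   pre-flight and post-flight collections.
#' @param dispersion negative-binomial size parameter for eggs per stem
#'   (smaller = more overdispersed; `Inf` gives Poisson).
#' @param egg_distribution `"nbinom"` (default; overdispersed, multiple
#'   females ovipositing in attractive stems), `"poisson"`, or `"fixed"`
#'   (every stem carries exactly `round(egg_intensity)` eggs, for
#'   degenerate-configuration checks).
#' @param site_years list of `list(site =, year =)` labels.
#' @param seed default RNG seed used by [simulate_cohort()].
#' @return a validated configuration list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 3, n_blocks = 3,
                       cultivars = default_cultivars(),
                       stems_per_plot = 1500, weeks = 9,
                       bags_per_plot = 3, stems_per_bag = 35,
                       stubs_per_collection = 25, dispersion = 1.2,
                       egg_distribution = c("nbinom", "poisson", "fixed"),
                       site_years = list(
                         list(site = "Amsterdam", year = 2016),
                         list(site = "Amsterdam", year = 2017),
                         list(site = "BigSandy", year = 2017)
                       ),
                       seed = NULL) {
  egg_distribution <- match.arg(egg_distribution)
  stopifnot(n_sites >= 1, n_blocks >= 1, stems_per_plot >= 1,
            weeks >= 1, weeks <= 9, bags_per_plot >= 1, stems_per_bag >= 1,
            stubs_per_collection >= 0, dispersion > 0)
  if (n_sites > length(site_years)) {
    stop("n_sites exceeds the number of site_year labels provided")
  }
  if (is.null(names(cultivars)) || any(!nzchar(names(cultivars)))) {
    stop("cultivars must be a named list")
  }
  for (cv in names(cultivars)) {
    p <- cultivars[[cv]]
    need <- c("egg_intensity", "p_plant_defense", "p_parasitism",
              "p_unknown_early", "p_pathogens", "p_unknown_late")
    missing <- setdiff(need, names(p))
    if (length(missing) > 0L) {
      stop("cultivar '", cv, "' is missing parameter(s): ",
           paste(missing, collapse = ", "))
    }
    if (p$egg_intensity < 0) stop("egg_intensity must be >= 0 (", cv, ")")
    probs <- unlist(p[setdiff(need, "egg_intensity")])
    if (any(probs < 0 | probs > 1)) {
      stop("cultivar '", cv, "' has probabilities outside [0, 1]")
    }
  }
  structure(list(
    n_sites = as.integer(n_sites), n_blocks = as.integer(n_blocks),
    cultivars = cultivars, stems_per_plot = as.integer(stems_per_plot),
    weeks = as.integer(weeks), bags_per_plot = as.integer(bags_per_plot),
    stems_per_bag = as.integer(stems_per_bag),
    stubs_per_collection = as.integer(stubs_per_collection),
    dispersion = dispersion, egg_distribution = egg_distribution,
    site_years = site_years[seq_len(n_sites)],
    seed = seed
  ), class = "sim_config")
}

#' Read a simulation configuration from a structured text file
#'
#' The file is YAML key-value text mirroring the arguments of
#' [sim_config()]; unknown keys are rejected by the validator.
#'
#' @param path configuration file path.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

# per-stem biology for one plot: egg load, staggered hatching, neonate
# plant-defense deaths, obligate-cannibalism resolution when the first
# surviving larva establishes, then the parasitism window and the
# overwintering stages.  Returns occupant-level fates plus per-stem summary.
.sim_plot_biology <- function(n_stems, pars, dispersion,
                              egg_distribution = "nbinom") {
  k <- switch(egg_distribution,
    fixed = rep(as.integer(round(pars$egg_intensity)), n_stems),
    poisson = stats::rpois(n_stems, pars$egg_intensity),
    nbinom = if (is.finite(dispersion)) {
      stats::rnbinom(n_stems, size = dispersion, mu = pars$egg_intensity)
    } else {
      stats::rpois(n_stems, pars$egg_intensity)
    }
  )
  occ_stem <- rep(seq_len(n_stems), k)
  n_occ <- length(occ_stem)
  if (n_occ == 0L) {
    occ <- data.frame(stem = integer(), occupant = integer(),
                      hatch_week = integer(), fate = character(),
                      stage = character(), cause = character(),
                      death_week = numeric(), stringsAsFactors = FALSE)
    return(list(k = k, occ = occ, winner = rep(NA_integer_, n_stems)))
  }
  occupant <- sequence(k[k > 0L])
  hatch_week <- sample(2:4, n_occ, replace = TRUE)
  pd_die <- stats::runif(n_occ) < pars$p_plant_defense

  # establishment: first plant-defense survivor (random tie-break) claims
  # the stem; one week later it has consumed every other occupant
  score <- ifelse(pd_die, Inf, hatch_week + stats::runif(n_occ) * 0.5)
  min_score <- rep(Inf, n_stems)
  agg <- tapply(score, occ_stem, min)
  min_score[as.integer(names(agg))] <- agg
  is_winner <- is.finite(score) & score == min_score[occ_stem]
  winner_hatch <- rep(NA_integer_, n_stems)
  winner_hatch[occ_stem[is_winner]] <- hatch_week[is_winner]
  res_week <- winner_hatch + 1L  # NA when no occupant survives plant defense

  fate <- character(n_occ)       # "alive" carried forward for the winner
  stage <- rep(NA_character_, n_occ)
  cause <- rep(NA_character_, n_occ)
  death_week <- rep(NA_real_, n_occ)

  has_winner <- !is.na(res_week[occ_stem])
  eaten_egg <- has_winner & !is_winner & hatch_week >= res_week[occ_stem]
  hatched_loser <- has_winner & !is_winner & !eaten_egg
  orphan <- !has_winner  # every occupant hatches and dies of plant defense

  fate[is_winner] <- "alive"
  fate[eaten_egg] <- "dead"
  stage[eaten_egg] <- "egg"
  cause[eaten_egg] <- "cannibalism"
  death_week[eaten_egg] <- res_week[occ_stem[eaten_egg]]

  i <- hatched_loser & pd_die
  fate[i] <- "dead"; stage[i] <- "larva_i"; cause[i] <- "plant_defense"
  death_week[i] <- hatch_week[i]
  i <- hatched_loser & !pd_die
  fate[i] <- "dead"; stage[i] <- "larva_i"; cause[i] <- "cannibalism"
  death_week[i] <- res_week[occ_stem[i]]

  fate[orphan] <- "dead"
  stage[orphan] <- "larva_i"
  cause[orphan] <- "plant_defense"
  death_week[orphan] <- hatch_week[orphan]

  # winner's later-stage competing risks; parasitism only in the vulnerable
  # window (Larva III), pathogens and late unknown factors while
  # overwintering (Larva IV pre-flight, Larva V post-flight)
  w_idx <- which(is_winner)
  nw <- length(w_idx)
  if (nw > 0L) {
    u <- matrix(stats::runif(nw * 6L), ncol = 6L)
    par3 <- u[, 1] < pars$p_parasitism
    unk3 <- !par3 & u[, 2] < pars$p_unknown_early
    path4 <- !par3 & !unk3 & u[, 3] < pars$p_pathogens
    unk4 <- !par3 & !unk3 & !path4 & u[, 4] < pars$p_unknown_late
    path5 <- !par3 & !unk3 & !path4 & !unk4 & u[, 5] < pars$p_pathogens
    unk5 <- !par3 & !unk3 & !path4 & !unk4 & !path5 & u[, 6] < pars$p_unknown_late
    adult <- !par3 & !unk3 & !path4 & !unk4 & !path5 & !unk5

    set_fate <- function(sel, stg, cs, dw = NA_real_) {
      j <- w_idx[sel]
      fate[j] <<- "dead"; stage[j] <<- stg; cause[j] <<- cs
      death_week[j] <<- dw
    }
    set_fate(par3, "larva_iii", "parasitism", 5)
    set_fate(unk3, "larva_iii", "unknown", 5)
    set_fate(path4, "larva_iv", "pathogens")
    set_fate(unk4, "larva_iv", "unknown")
    set_fate(path5, "larva_v", "pathogens")
    set_fate(unk5, "larva_v", "unknown")
    fate[w_idx[adult]] <- "adult"
    stage[w_idx[adult]] <- "adult"
  }

  occ <- data.frame(stem = occ_stem, occupant = occupant,
                    hatch_week = hatch_week, is_winner = is_winner,
                    fate = fate, stage = stage, cause = cause,
                    death_week = death_week, stringsAsFactors = FALSE)
  list(k = k, occ = occ)
}

# paste evidence groups for dead occupants of one stem into a cell
.evidence_cell <- function(groups) paste(groups, collapse = ";")

# evidence emitted for one death, by stage and cause
.death_evidence <- function(stage, cause, larva_present = FALSE) {
  out <- character(length(stage))
  eaten <- stage == "egg"
  out[eaten & larva_present] <- "LARVA_PLUS_EGG"
  out[eaten & !larva_present] <- "MULTIPLE_EGGS"
  out[stage == "larva_i" & cause == "plant_defense"] <- "DEAD_NEONATE"
  out[stage == "larva_i" & cause == "cannibalism"] <- "MULTIPLE_LARVAE"
  out[stage == "larva_iii" & cause == "parasitism"] <- "PARASITOID_COCOON"
  out[stage == "larva_iii" & cause == "unknown"] <- "DEAD_MULTI_INTERNODE"
  out[stage == "larva_iv" & cause == "pathogens"] <- "WHITE_PINK_HYPHAE"
  out[stage == "larva_iv" & cause == "unknown"] <- "DEAD_MULTI_INTERNODE"
  out[stage == "larva_v" & cause == "pathogens"] <- "PINK_CADAVER"
  out[stage == "larva_v" & cause == "unknown"] <- "DEAD_MULTI_INTERNODE"
  out
}

.record_row <- function(meta, sample_kind, week, stub_phase, unit_id,
                        n_eggs, n_live, evidence, emerged) {
  data.frame(site = meta$site, year = meta$year, cultivar = meta$cultivar,
             block = meta$block, plot = meta$plot,
             sample_kind = sample_kind, week = week, stub_phase = stub_phase,
             unit_id = unit_id, n_eggs = n_eggs, n_live_larvae = n_live,
             dead_evidence = evidence, emerged = emerged,
             stringsAsFactors = FALSE)
}

# census emission: every occupant is reported exactly once per stage it was
# alive at entry to -- alive if it survived the stage, as a dead observation
# in the stage it died.  Aggregating these records (prospective = FALSE)
# reproduces the ground-truth event log exactly.
.emit_census <- function(bio, meta) {
  occ <- bio$occ
  k <- bio$k
  stems <- which(k > 0L)
  if (length(stems) == 0L) return(NULL)
  sid <- sprintf("%s_%s_s%04d", meta$block, meta$plot_code, stems)
  names(sid) <- as.character(stems)

  rows <- list()
  emit <- function(stem_ids, kind, week, phase, n_eggs, n_live, ev, emerged) {
    rows[[length(rows) + 1L]] <<- .record_row(
      meta, kind, week, phase, sid[as.character(stem_ids)],
      n_eggs, n_live, ev, emerged)
  }
  count_by <- function(idx) {
    out <- integer(length(stems))
    names(out) <- as.character(stems)
    if (length(idx) > 0L) {
      tt <- table(occ$stem[idx])
      out[names(tt)] <- as.integer(tt)
    }
    out
  }
  ev_by <- function(idx, larva_present = rep(FALSE, length(idx))) {
    out <- rep("", length(stems))
    names(out) <- as.character(stems)
    if (length(idx) > 0L) {
      ev <- .death_evidence(occ$stage[idx], occ$cause[idx], larva_present)
      agg <- tapply(ev, occ$stem[idx], .evidence_cell)
      out[names(agg)] <- unname(agg)
    }
    out
  }

  # egg stage: alive = survived the egg stage (hatched), dead = eaten eggs
  eaten <- which(occ$stage %in% "egg")
  hatched_n <- count_by(which(!(seq_len(nrow(occ)) %in% eaten)))
  eaten_ev <- ev_by(eaten, larva_present = rep(FALSE, length(eaten)))
  emit(stems, "stem", 1L, NA_character_, unname(hatched_n), 0L,
       unname(eaten_ev), FALSE)

  # Larva I: entrants are all hatched occupants
  died_i <- which(occ$stage %in% "larva_i")
  alive_i <- count_by(which(occ$fate %in% c("alive", "adult") |
                              occ$stage %in% c("larva_iii", "larva_iv", "larva_v")))
  ev_i <- ev_by(died_i)
  sel <- unname(alive_i) > 0L | nzchar(unname(ev_i))
  if (any(sel)) {
    emit(stems[sel], "stem", 3L, NA_character_, 0L, unname(alive_i)[sel],
         unname(ev_i)[sel], FALSE)
  }

  # Larva III: entrants are winners that reached the vulnerable window
  died_iii <- which(occ$stage %in% "larva_iii")
  alive_iii <- count_by(which(occ$fate %in% c("alive", "adult") |
                                occ$stage %in% c("larva_iv", "larva_v")))
  ev_iii <- ev_by(died_iii)
  sel <- unname(alive_iii) > 0L | nzchar(unname(ev_iii))
  if (any(sel)) {
    emit(stems[sel], "stem", 7L, NA_character_, 0L, unname(alive_iii)[sel],
         unname(ev_iii)[sel], FALSE)
  }

  # Larva IV: pre-flight stubs
  died_iv <- which(occ$stage %in% "larva_iv")
  alive_iv <- count_by(which(occ$fate %in% c("alive", "adult") |
                               occ$stage %in% "larva_v"))
  ev_iv <- ev_by(died_iv)
  sel <- unname(alive_iv) > 0L | nzchar(unname(ev_iv))
  if (any(sel)) {
    emit(stems[sel], "stub", NA_integer_, "pre_flight", 0L,
         unname(alive_iv)[sel], unname(ev_iv)[sel], FALSE)
  }

  # Larva V: post-flight stubs; survivors emerge as adults
  died_v <- which(occ$stage %in% "larva_v")
  adult <- count_by(which(occ$fate %in% "adult"))
  ev_v <- ev_by(died_v)
  sel <- unname(adult) > 0L | nzchar(unname(ev_v))
  if (any(sel)) {
    emit(stems[sel], "stub", NA_integer_, "post_flight", 0L, 0L,
         unname(ev_v)[sel], unname(adult)[sel] > 0L)
  }

  do.call(rbind, rows)
}

# survey emission: the field design.  Weekly destructive cross-sections of
# the stand (each stem dissected at most once) and stub collections drawn
# from cut stems among the stems never taken in summer.  A sampled stem is
# scored as a dissector would at that occasion: live occupants by stage,
# dead occupants only while their evidence is fresh (the sampling window in
# which the death occurred); older remains are not re-scored.
.emit_survey <- function(bio, meta, cfg) {
  occ <- bio$occ
  k <- bio$k
  n_stems <- length(k)
  weekly_n <- cfg$bags_per_plot * cfg$stems_per_bag
  demand <- cfg$weeks * weekly_n
  if (demand > n_stems) {
    stop("infeasible sampling: ", demand, " stems requested per plot but ",
         "the stand has only ", n_stems)
  }
  sampled <- sample.int(n_stems, demand)
  samp_week <- rep(seq_len(cfg$weeks), each = weekly_n)

  sid <- sprintf("%s_%s_s%04d", meta$block, meta$plot_code, seq_len(n_stems))

  window_of <- function(w) ifelse(w <= 1, 1L, ifelse(w <= 4, 2L, 3L))

  rows <- list()

  # weekly stem cross-sections
  idx_of_stem <- match(occ$stem, sampled)
  w_of_occ <- samp_week[idx_of_stem]        # NA when the stem is never sampled
  has <- !is.na(w_of_occ)
  n_eggs_v <- integer(demand)
  n_live_v <- integer(demand)
  ev_v <- character(demand)
  if (any(has)) {
    o <- occ[has, ]
    w <- w_of_occ[has]
    slot <- idx_of_stem[has]
    # egg phase: an occupant is an egg until it hatches or is consumed
    egg_until <- ifelse(o$stage %in% "egg" & !is.na(o$death_week),
                        o$death_week, o$hatch_week)
    live_egg <- w < egg_until
    # larval phase: hatched and not yet dead (stub-stage deaths never show
    # in summer samples; their death_week is NA)
    dw <- ifelse(is.na(o$death_week), Inf, o$death_week)
    hatched <- !(o$stage %in% "egg") & o$hatch_week <= w
    live_larva <- hatched & dw > w
    dead_vis <- !is.na(o$cause) & !is.na(o$death_week) &
      o$death_week <= w & window_of(o$death_week) == window_of(w) &
      o$stage %in% c("egg", "larva_i", "larva_iii")

    n_eggs_v <- as.integer(tapply(live_egg, factor(slot, levels = seq_len(demand)), sum))
    n_eggs_v[is.na(n_eggs_v)] <- 0L
    n_live_v <- as.integer(tapply(live_larva, factor(slot, levels = seq_len(demand)), sum))
    n_live_v[is.na(n_live_v)] <- 0L
    if (any(dead_vis)) {
      lp <- n_live_v[slot] > 0L
      ev <- .death_evidence(o$stage[dead_vis], o$cause[dead_vis], lp[dead_vis])
      agg <- tapply(ev, factor(slot[dead_vis], levels = seq_len(demand)),
                    .evidence_cell)
      ev_v[!is.na(agg)] <- agg[!is.na(agg)]
    }
  }
  rows[[1L]] <- .record_row(meta, "stem", samp_week, NA_character_,
                            sid[sampled], n_eggs_v, n_live_v, ev_v, FALSE)

  # stub collections: cut stems are those whose larva survived the summer
  # stages (reached Larva IV); only stems not destroyed in summer sampling
  # remain in the ground
  reached_iv <- occ$stem[occ$fate %in% c("alive", "adult") |
                           occ$stage %in% c("larva_iv", "larva_v")]
  cut_stems <- setdiff(reached_iv, sampled)
  draw_stubs <- function(pool, phase) {
    want <- cfg$stubs_per_collection
    if (want == 0L) return(integer(0))
    if (length(pool) < want) {
      warning("plot ", meta$plot, " (", meta$site, " ", meta$year, "): only ",
              length(pool), " stubs available for the ", phase,
              " collection (", want, " requested)")
      want <- length(pool)
    }
    pool[sample.int(length(pool), want)]
  }
  pre <- draw_stubs(cut_stems, "pre_flight")
  if (length(pre) > 0L) {
    o <- occ[occ$is_winner & occ$stem %in% pre, ]
    o <- o[match(pre, o$stem), ]
    dead4 <- o$stage %in% "larva_iv"
    ev <- rep("", length(pre))
    ev[dead4] <- .death_evidence(o$stage[dead4], o$cause[dead4])
    rows[[length(rows) + 1L]] <- .record_row(
      meta, "stub", NA_integer_, "pre_flight", sid[pre],
      0L, as.integer(!dead4), ev, FALSE)
  }
  post_pool <- setdiff(cut_stems, pre)
  post <- draw_stubs(post_pool, "post_flight")
  if (length(post) > 0L) {
    o <- occ[occ$is_winner & occ$stem %in% post, ]
    o <- o[match(post, o$stem), ]
    dead5 <- o$stage %in% "larva_v"
    dead4 <- o$stage %in% "larva_iv"  # old cadaver, not re-scored
    emerged <- o$fate %in% "adult"
    ev <- rep("", length(post))
    ev[dead5] <- .death_evidence(o$stage[dead5], o$cause[dead5])
    rows[[length(rows) + 1L]] <- .record_row(
      meta, "stub", NA_integer_, "post_flight", sid[post],
      0L, 0L, ev, emerged)
  }
  do.call(rbind, rows)
}

#' Simulate a stage-structured competing-risks cohort with known truth
#'
#' Generates dissection records for a replicated field design together with
#' the ground-truth event log of every simulated death.  Within each stem,
#' eggs hatch in a staggered order; each neonate independently survives or
#' dies of plant defense at emergence; the first surviving larva claims the
#' stem and, one week later, has consumed every other occupant (eggs die of
#' cannibalism at the egg stage, hatched rivals at Larva I), so at most one
#' occupant survives per stem.  The survivor then runs the parasitism
#' window (Larva III) and the overwintering stages (Larva IV, Larva V) with
#' pathogen and unknown-factor risks, emerging as an adult if it survives.
#'
#' Two sampling operators are available.  `"survey"` emulates the field
#' design: weekly destructive cross-sections (each stem dissected at most
#' once) plus pre- and post-flight stub collections, scored as a dissector
#' would score them at the sampling occasion; it carries the field method's
#' approximations.  `"census"` reports every occupant exactly once per
#' stage, so that [aggregate_counts()] with `prospective = FALSE`
#' reproduces the ground-truth tallies exactly; use it for estimator
#' validation.
#'
#' @param config a [sim_config()].
#' @param sampling `"survey"` or `"census"`.
#' @param seed RNG seed (defaults to `config$seed`).  Per-plot streams are
#'   derived hierarchically from it, so enlarging the design does not
#'   perturb existing plots' draws.
#' @return a list with elements `records` (a validated
#'   `dissection_records` data.frame), `truth` (see below) and `sampling`.
#'   `truth` is a list with `events` (one row per simulated death: stratum
#'   labels, stem, occupant, stage, cause), `stems` (one row per occupied
#'   stem: egg load and whether its occupant emerged), `cohort` (eggs laid
#'   per stratum), `n_adults`, `decrements` (pooled ground-truth `ad_ix`
#'   matrix), `cause_totals`, and `final_survival`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            sampling = c("survey", "census"),
                            seed = config$seed) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(config, "sim_config"))

  plots <- expand.grid(
    cultivar = names(config$cultivars),
    block = paste0("B", seq_len(config$n_blocks)),
    site_idx = seq_len(config$n_sites),
    stringsAsFactors = FALSE
  )
  rec_parts <- vector("list", nrow(plots))
  ev_parts <- vector("list", nrow(plots))
  stem_parts <- vector("list", nrow(plots))
  cohort_parts <- vector("list", nrow(plots))

  for (p in seq_len(nrow(plots))) {
    sy <- config$site_years[[plots$site_idx[p]]]
    cv <- plots$cultivar[p]
    meta <- list(site = sy$site, year = sy$year, cultivar = cv,
                 block = plots$block[p],
                 plot = paste0(plots$block[p], "_", cv),
                 plot_code = substr(cv, 1, 3))
    if (!is.null(seed)) {
      set.seed((as.integer(seed) %% 1000003L) * 2048L + p)
    }
    bio <- .sim_plot_biology(config$stems_per_plot, config$cultivars[[cv]],
                             config$dispersion, config$egg_distribution)
    rec_parts[[p]] <- if (sampling == "census") {
      .emit_census(bio, meta)
    } else {
      .emit_survey(bio, meta, config)
    }
    occ <- bio$occ
    dead <- occ[occ$fate == "dead", , drop = FALSE]
    if (nrow(dead) > 0L) {
      ev_parts[[p]] <- data.frame(
        site = meta$site, year = meta$year, cultivar = cv,
        block = meta$block, plot = meta$plot,
        stem = dead$stem, occupant = dead$occupant,
        stage = dead$stage, cause = dead$cause, stringsAsFactors = FALSE)
    }
    occupied <- which(bio$k > 0L)
    stem_parts[[p]] <- data.frame(
      site = meta$site, year = meta$year, cultivar = cv, block = meta$block,
      plot = meta$plot, stem = occupied, eggs = bio$k[occupied],
      adult = occupied %in% occ$stem[occ$fate == "adult"],
      stringsAsFactors = FALSE)
    cohort_parts[[p]] <- data.frame(
      site = meta$site, year = meta$year, cultivar = cv, block = meta$block,
      plot = meta$plot, eggs = as.integer(sum(bio$k)),
      adults = as.integer(sum(occ$fate == "adult")), stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, rec_parts[!vapply(rec_parts, is.null, logical(1))])
  if (is.null(records)) {
    records <- .record_row(list(site = character(0), year = integer(0),
                                cultivar = character(0), block = character(0),
                                plot = character(0)),
                           character(0), integer(0), character(0),
                           character(0), integer(0), integer(0),
                           character(0), logical(0))
  }
  rownames(records) <- NULL
  class(records) <- c("dissection_records", "data.frame")
  attr(records, "diagnostics") <- data.frame(row = integer(),
                                             message = character(),
                                             stringsAsFactors = FALSE)

  events <- do.call(rbind, ev_parts[!vapply(ev_parts, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(site = character(), year = integer(),
                         cultivar = character(), block = character(),
                         plot = character(), stem = integer(),
                         occupant = integer(), stage = character(),
                         cause = character(), stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, cohort_parts)
  total_eggs <- as.integer(sum(cohort$eggs))

  dec <- matrix(0, nrow = length(stage_levels()) - 1L,
                ncol = length(mortality_causes()),
                dimnames = list(setdiff(stage_levels(), "adult"),
                                mortality_causes()))
  if (nrow(events) > 0L && total_eggs > 0L) {
    tt <- table(factor(events$stage, levels = rownames(dec)),
                factor(events$cause, levels = colnames(dec)))
    dec <- dec + as.matrix(tt) / total_eggs
  }
  truth <- list(
    events = events,
    stems = do.call(rbind, stem_parts),
    cohort = cohort,
    total_eggs = total_eggs,
    n_adults = sum(cohort$adults),
    decrements = dec,
    cause_totals = colSums(dec),
    final_survival = if (total_eggs > 0L) sum(cohort$adults) / total_eggs else NA_real_
  )
  list(records = records, truth = truth, sampling = sampling)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    total_eggs = truth$total_eggs,
    n_adults = truth$n_adults,
    final_survival = truth$final_survival,
    cause_totals = as.list(truth$cause_totals),
    decrements = apply(truth$decrements, 1, as.list, simplify = FALSE),
    cohort = truth$cohort
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare pipeline estimates against simulation ground truth
#'
#' Aggregates the simulated records, fits the pooled life table, and
#' compares the estimated crude cause totals `aD_i` (and the derived net
#' probabilities) against the simulator's ground truth, reporting absolute
#' errors and binomial standard errors at the simulated cohort size.
#'
#' @param sim a [simulate_cohort()] result.
#' @param prospective passed to [aggregate_counts()]; defaults to the
#'   convention matching the sampling mode (surplus-occupancy scoring for
#'   survey records, explicit evidence only for census records).
#' @return an object of class `mdlt_recovery`: a data.frame with one row
#'   per cause (`truth`, `estimate`, `abs_error`, `se`, `z`), with the
#'   fitted table and net-probability comparison attached as attributes.
#' @export
recovery_report <- function(sim, prospective = identical(sim$sampling, "survey")) {
  counts <- aggregate_counts(sim$records, by = NULL, prospective = prospective)
  fit <- mdlt(counts, stratum = "pooled", skip_empty_stages = TRUE)
  est <- cause_totals(fit)
  tru <- sim$truth$cause_totals
  n <- sim$truth$total_eggs
  se <- sqrt(pmax(tru * (1 - tru), 1e-12) / n)
  out <- data.frame(
    cause = names(tru),
    truth = unname(tru),
    estimate = unname(est[names(tru)]),
    abs_error = unname(abs(est[names(tru)] - tru)),
    se = unname(se),
    stringsAsFactors = FALSE
  )
  out$z <- ifelse(out$se > 0, out$abs_error / out$se, 0)
  q_est <- tryCatch(net_probabilities(est), error = function(e) NULL)
  q_tru <- tryCatch(net_probabilities(tru), error = function(e) NULL)
  structure(out, class = c("mdlt_recovery", "data.frame"),
            fit = fit, n = n, q_estimate = q_est, q_truth = q_tru)
}

#' @export
print.mdlt_recovery <- function(x, ...) {
  cat("Recovery of ground-truth crude cause totals (cohort of ",
      attr(x, "n"), " eggs)\n\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
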