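#' Simulator configuration
#'
#' All tunables of the lattice tumor-immune simulator. The geometry
#' defaults reproduce the reference setup at desk scale: a flattened box
#' of 100 x 100 x 10 voxels (2 x 2 x 0.2 mm at 20 um voxels) seeded with a
#' centered block of 25 x 25 x 4 voxels holding one cancer cell each, 10%
#' of them stem-like (CSC) and the rest progenitors; there are no immune
#' cells at the start. The full-scale domain (10 x 10 x 0.2 mm, 2.5
#' million voxels) is available via `dims = c(500, 500, 10)`.
#'
#' Dosing: a single anti-PD-1 dose at `dose_day` (day 25), 3 mg/kg for the
#' high-dose scenario, 0.3 mg/kg for low-dose, 0 for no treatment. The
#' plasma level follows a one-compartment exponential decay
#' ([drug_concentration()]) and gates T-cell killing through a Hill
#' blockade factor ([pd1_blockade_factor()]).
#'
#' Division, recruitment and killing rates are per-day; per-step event
#' probabilities are `rate * time_step` (all well below 1 at the
#' defaults). Defaults are calibrated so that, at desk scale, the
#' untreated tumor grows steadily over the 180-day course while the
#' high-dose case regresses.
#'
#' @param dims Integer box dimensions in voxels, default `c(100, 100, 10)`.
#' @param voxel_size Voxel edge in micrometers (20).
#' @param seed_block Seeded block in voxels, default `c(25, 25, 4)`,
#'   centered.
#' @param csc_fraction Fraction of seeded cells that are CSC (0.10); the
#'   CSC count is deterministic (`round(csc_fraction * n_seed)`), their
#'   placement random.
#' @param time_step Step in days (0.25).
#' @param duration Simulated time in days (180).
#' @param dose Anti-PD-1 dose in mg/kg (3 = HD, 0.3 = LD, 0 = NT).
#' @param dose_day Day the dose is applied (25).
#' @param pk_half_life Effective half-life of target engagement in
#'   days (60): checkpoint receptor occupancy outlasts the plasma
#'   antibody, so the surrogate decays slowly.
#' @param ec50 Plasma level giving half-maximal PD-1 blockade, mg/kg
#'   (0.5: the low 0.3 mg/kg dose starts below half-maximal blockade,
#'   the 3 mg/kg dose near saturation).
#' @param base_kill_prob Per-contact, per-step kill probability of an
#'   active CD8+ cell at full blockade (0.6).
#' @param treg_suppression_factor Multiplier on the kill probability when
#'   a Treg is Moore-adjacent to the killer (0.5).
#' @param entry_point_density Per-step probability that an eligible voxel
#'   (one with a cancer cell in its 26-voxel Moore neighborhood) hosts a
#'   vascular entry point (0.002); entry points are resampled every step
#'   because the tumor boundary moves.
#' @param cd8_recruit_rate,treg_recruit_rate Recruitment rates at each
#'   entry point, cells/day (1.2 and 0.3).
#' @param csc_division_rate CSC division rate, 1/day (0.12).
#' @param p_sym Probability a CSC division is symmetric (CSC + CSC) rather
#'   than producing a progenitor (0.3).
#' @param prog_division_rate Progenitor division rate, 1/day (0.3).
#' @param max_divisions Progenitor division potential; a cell that uses it
#'   up becomes senescent (4).
#' @param senescent_lifespan Days a senescent cell survives (20).
#' @param cyt_kill_threshold Kills after which an effector cell becomes
#'   cytotoxic (1).
#' @param exhaust_kill_threshold Kills after which a CD8+ cell becomes
#'   exhausted and stops killing (8).
#' @param il2_source,ifng_source Cytokine source strength deposited at a
#'   kill site (concentration units/day).
#' @param D_cytokine Cytokine diffusivity, um^2/day (200; the explicit
#'   solver requires `time_step <= voxel_size^2 / (6 D)`).
#' @param cytokine_decay Cytokine decay rate, 1/day (1).
#' @param random_seed Base seed; replicate r runs with
#'   `random_seed + r`.
#' @param n_replicates Number of stochastic replicates (10).
#' @return A `sim_config` object.
#' @export
sim_config <- function(dims = c(100L, 100L, 10L), voxel_size = 20,
                       seed_block = c(25L, 25L, 4L), csc_fraction = 0.10,
                       time_step = 0.25, duration = 180,
                       dose = 3, dose_day = 25, pk_half_life = 60,
                       ec50 = 0.5, base_kill_prob = 0.6,
                       treg_suppression_factor = 0.5,
                       entry_point_density = 0.002,
                       cd8_recruit_rate = 1.2, treg_recruit_rate = 0.3,
                       csc_division_rate = 0.12, p_sym = 0.3,
                       prog_division_rate = 0.3, max_divisions = 4L,
                       senescent_lifespan = 20,
                       cyt_kill_threshold = 1L,
                       exhaust_kill_threshold = 8L,
                       il2_source = 1, ifng_source = 1,
                       D_cytokine = 200, cytokine_decay = 1,
                       random_seed = 1L, n_replicates = 10L) {
  dims <- as.integer(dims); seed_block <- as.integer(seed_block)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be three positive voxel counts", call. = FALSE)
  if (length(seed_block) != 3L || any(seed_block < 1L))
    stop("seed_block must be three positive voxel counts", call. = FALSE)
  if (any(seed_block > dims))
    stop("seed block larger than the box", call. = FALSE)
  probs <- c(csc_fraction, p_sym, base_kill_prob,
             treg_suppression_factor, entry_point_density)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (time_step <= 0 || duration <= 0)
    stop("time_step and duration must be > 0", call. = FALSE)
  if (D_cytokine > 0 && time_step > voxel_size^2 / (6 * D_cytokine))
    stop("time_step violates the diffusion stability bound h^2/(6D)",
         call. = FALSE)
  step_probs <- time_step * c(csc_division_rate, prog_division_rate,
                              cd8_recruit_rate, treg_recruit_rate)
  if (any(step_probs > 1))
    stop("a rate * time_step exceeds 1; reduce the rate or the step",
         call. = FALSE)
  cfg <- list(dims = dims, voxel_size = voxel_size, seed_block = seed_block,
              csc_fraction = csc_fraction, time_step = time_step,
              duration = duration, dose = dose, dose_day = dose_day,
              pk_half_life = pk_half_life, ec50 = ec50,
              base_kill_prob = base_kill_prob,
              treg_suppression_factor = treg_suppression_factor,
              entry_point_density = entry_point_density,
              cd8_recruit_rate = cd8_recruit_rate,
              treg_recruit_rate = treg_recruit_rate,
              csc_division_rate = csc_division_rate, p_sym = p_sym,
              prog_division_rate = prog_division_rate,
              max_divisions = as.integer(max_divisions),
              senescent_lifespan = senescent_lifespan,
              cyt_kill_threshold = as.integer(cyt_kill_threshold),
              exhaust_kill_threshold = as.integer(exhaust_kill_threshold),
              il2_source = il2_source, ifng_source = ifng_source,
              D_cytokine = D_cytokine, cytokine_decay = cytokine_decay,
              random_seed = as.integer(random_seed),
              n_replicates = as.integer(n_replicates))
  structure(cfg, class = "sim_config")
}

#' Number of voxels in the simulation box
#' @param cfg A [sim_config()].
#' @return `prod(dims)`.
#' @export
n_voxels <- function(cfg) prod(as.numeric(cfg$dims))

#' Preset scenario configurations
#'
#' The four dosing scenarios: no treatment (`NT`, 0 mg/kg), low dose
#' (`LD`, 0.3 mg/kg), high dose (`HD`, 3 mg/kg) and high dose with
#' tenfold vascular entry-point density (`HDV`, emulating an
#' immune-infiltrated, low-tumor-purity microenvironment).
#'
#' @param scenario One of `"NT"`, `"LD"`, `"HD"`, `"HDV"`.
#' @param scale `"test"` (100 x 100 x 10 voxel box, the default) or
#'   `"paper"` (500 x 500 x 10).
#' @param ... Further overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
scenario_config <- function(scenario = c("HD", "LD", "NT", "HDV"),
                            scale = c("test", "paper"), ...) {
  scenario <- match.arg(scenario)
  scale <- match.arg(scale)
  args <- list(...)
  args$dims <- args$dims %||%
    if (scale == "paper") c(500L, 500L, 10L) else c(100L, 100L, 10L)
  args$dose <- switch(scenario, NT = 0, LD = 0.3, HD = 3, HDV = 3)
  if (scenario == "HDV")
    args$entry_point_density <-
      10 * (args$entry_point_density %||% formals(sim_config)$entry_point_density)
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plasma drug level of the one-compartment PK surrogate
#'
#' Zero before the dose day, then a single-dose exponential decay:
#' `dose * 2^(-(t - dose_day) / pk_half_life)`.
#'
#' @param t Time in days (vectorized).
#' @param cfg A [sim_config()].
#' @return Plasma level in mg/kg equivalents.
#' @export
drug_concentration <- function(t, cfg) {
  ifelse(t < cfg$dose_day, 0,
         cfg$dose * exp(-log(2) * (t - cfg$dose_day) / cfg$pk_half_life))
}

#' PD-1 blockade factor
#'
#' Hill function `conc / (conc + ec50)` in `[0, 1)`; multiplies the base
#' kill probability to give the effective per-contact kill probability,
#' so killing is fully checkpoint-gated: no drug, no killing.
#'
#' @param conc Plasma level (vectorized, >= 0).
#' @param cfg A [sim_config()].
#' @return Fraction in `[0, 1]`.
#' @export
pd1_blockade_factor <- function(conc, cfg) conc / (conc + cfg$ec50)

# ---- lattice helpers --------------------------------------------------

# 26 Moore offsets (optionally 27 with the center), built once
.moore_off27 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g)
})
.moore_off26 <- .moore_off27[rowSums(.moore_off27 != 0) > 0, ]
moore_offsets <- function(include_self = FALSE)
  if (include_self) .moore_off27 else .moore_off26


# For a vector of linear voxel indices, all valid Moore-neighbor pairs.
# Returns list(src = position into idx, nbr = linear neighbor index).
moore_pairs <- function(idx, dims, include_self = FALSE) {
  m <- length(idx)
  if (m == 0L) return(list(src = integer(), nbr = integer()))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i0 <- (idx - 1L) %% nx + 1L
  j0 <- ((idx - 1L) %/% nx) %% ny + 1L
  k0 <- (idx - 1L) %/% (nx * ny) + 1L
  off <- moore_offsets(include_self)
  src_l <- vector("list", nrow(off)); nbr_l <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    ii <- i0 + off[o, 1]; jj <- j0 + off[o, 2]; kk <- k0 + off[o, 3]
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny & kk >= 1L & kk <= nz
    src_l[[o]] <- which(ok)
    nbr_l[[o]] <- ii[ok] + nx * (jj[ok] - 1L) + nx * ny * (kk[ok] - 1L)
  }
  list(src = unlist(src_l, use.names = FALSE),
       nbr = unlist(nbr_l, use.names = FALSE))
}

# pick, for each distinct src, one pair uniformly at random;
# returns indices into the pair vectors
pick_one_per_src <- function(src) {
  if (!length(src)) return(integer())
  r <- runif(length(src))
  o <- order(src, r)
  o[!duplicated(src[o])]
}

# immune capacity of each listed voxel: 8 if cancer-free, else 1
immune_capacity <- function(can_type, vox) ifelse(can_type[vox] > 0L, 1L, 8L)

# ---- state ------------------------------------------------------------

#' Initialize the lattice state
#'
#' Places one cancer cell in every voxel of the centered seed block;
#' exactly `round(csc_fraction * n_seed)` of them are CSC at random
#' positions within the block, the rest progenitors with full division
#' potential. No immune cells, zero cytokine fields, clock at 0.
#'
#' @param cfg A [sim_config()].
#' @return A `lattice_state` object.
#' @export
init_state <- function(cfg) {
  dims <- cfg$dims
  nvox <- prod(dims)
  lo <- (dims - cfg$seed_block) %/% 2L + 1L
  hi <- lo + cfg$seed_block - 1L
  block <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                 k = lo[3]:hi[3]))
  vox <- block[, 1] + dims[1] * (block[, 2] - 1L) +
    dims[1] * dims[2] * (block[, 3] - 1L)
  n_seed <- length(vox)
  n_csc <- round(cfg$csc_fraction * n_seed)
  can_type <- integer(nvox)
  can_type[vox] <- 2L # progenitor
  can_type[sample(vox, n_csc)] <- 1L # CSC
  state <- list(
    dims = dims, nvox = nvox,
    can_type = can_type,            # 0 none, 1 CSC, 2 progenitor, 3 senescent
    can_div = integer(nvox),        # progenitor divisions used
    can_age = numeric(nvox),        # senescent age, days
    imm_vox = integer(), imm_type = integer(), # 1 EFF, 2 CYT, 3 EXH, 4 TREG
    imm_kills = integer(),
    imm_count = integer(nvox),
    entry_points = integer(),
    il2 = array(0, dims), ifng = array(0, dims),
    clock = 0,
    events = list(births = 0L, kills = 0L, senescent_deaths = 0L))
  class(state) <- "lattice_state"
  state
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf(
    "<lattice_state> t = %g d | cancer %d (CSC %d, prog %d, sen %d) | immune %d\n",
    x$clock, sum(x$can_type > 0L), sum(x$can_type == 1L),
    sum(x$can_type == 2L), sum(x$can_type == 3L), length(x$imm_vox)))
  invisible(x)
}

#' Check the lattice invariants
#'
#' Verifies the per-voxel capacity rule (a voxel holds one cancer cell
#' plus at most one immune cell, or no cancer cell and at most eight
#' immune cells) and that the cached immune occupancy matches the cell
#' list. Errors on violation; used by the test suite after every step of
#' small runs.
#'
#' @param state A `lattice_state`.
#' @return Invisibly `TRUE`.
#' @export
validate_state <- function(state) {
  occ <- tabulate(state$imm_vox, nbins = state$nvox)
  if (!identical(occ, state$imm_count))
    stop("immune occupancy cache out of sync", call. = FALSE)
  cap <- ifelse(state$can_type > 0L, 1L, 8L)
  if (any(occ > cap))
    stop("capacity invariant violated", call. = FALSE)
  invisible(TRUE)
}

# ---- one step ---------------------------------------------------------

#' Advance the lattice state by one time step
#'
#' Applies the step phases in fixed order: cancer division and
#' senescence/death; vascular entry-point refresh; CD8+/Treg recruitment;
#' immune random-walk movement; checkpoint-gated killing with Treg
#' suppression and effector-to-cytotoxic-to-exhausted progression;
#' cytokine deposition at kill sites; explicit finite-volume cytokine
#' diffusion. All randomness is drawn from the R session RNG, so a run is
#' fully reproducible from `(config, seed)`.
#'
#' @param state A `lattice_state`.
#' @param cfg The [sim_config()] it was built with.
#' @return The updated state; `state$events` holds the step's birth,
#'   kill and senescent-death counts.
#' @export
advance <- function(state, cfg) {
  dims <- state$dims
  dt <- cfg$time_step
  births <- 0L; kills <- 0L; sen_deaths <- 0L

  ## (1) cancer division, senescence, senescent death
  csc <- which(state$can_type == 1L)
  prog <- which(state$can_type == 2L)
  div_csc <- csc[runif(length(csc)) < cfg$csc_division_rate * dt]
  div_prog <- prog[runif(length(prog)) < cfg$prog_division_rate * dt]
  dividers <- c(div_csc, div_prog)
  if (length(dividers)) {
    mp <- moore_pairs(dividers, dims)
    open <- state$can_type[mp$nbr] == 0L & state$imm_count[mp$nbr] <= 1L
    src <- mp$src[open]; nbr <- mp$nbr[open]
    sel <- pick_one_per_src(src)
    # resolve collisions on the same target voxel: random winner
    sel <- sel[sample.int(length(sel))]
    sel <- sel[!duplicated(nbr[sel])]
    parent <- dividers[src[sel]]
    target <- nbr[sel]
    is_csc <- state$can_type[parent] == 1L
    if (any(is_csc)) {
      tg <- target[is_csc]
      sym <- runif(length(tg)) < cfg$p_sym
      state$can_type[tg] <- ifelse(sym, 1L, 2L)
      state$can_div[tg] <- 0L
    }
    if (any(!is_csc)) {
      p <- parent[!is_csc]; tg <- target[!is_csc]
      new_div <- state$can_div[p] + 1L
      state$can_div[p] <- new_div
      state$can_type[tg] <- 2L
      state$can_div[tg] <- new_div
      spent <- new_div >= cfg$max_divisions
      if (any(spent)) {
        worn <- c(p[spent], tg[spent])
        state$can_type[worn] <- 3L
        state$can_age[worn] <- 0
      }
    }
    births <- births + length(target)
  }
  sen <- which(state$can_type == 3L)
  if (length(sen)) {
    state$can_age[sen] <- state$can_age[sen] + dt
    dead <- sen[state$can_age[sen] >= cfg$senescent_lifespan]
    if (length(dead)) {
      state$can_type[dead] <- 0L
      state$can_div[dead] <- 0L
      state$can_age[dead] <- 0
      sen_deaths <- length(dead)
    }
  }

  ## (2) entry-point refresh: voxels with a cancer cell in their Moore
  ##     neighborhood are eligible
  occ <- as.integer(state$can_type > 0L)
  elig_idx <- which(moore_count_cpp(occ, dims) >= 1L) # cancer in Moore nbhd
  state$entry_points <-
    elig_idx[runif(length(elig_idx)) < cfg$entry_point_density]

  ## (3) recruitment at entry points, capacity permitting
  ep <- state$entry_points
  if (length(ep)) {
    rec_cd8 <- ep[runif(length(ep)) < cfg$cd8_recruit_rate * dt]
    free <- immune_capacity(state$can_type, rec_cd8) -
      state$imm_count[rec_cd8]
    rec_cd8 <- rec_cd8[free >= 1L]
    if (length(rec_cd8)) {
      state$imm_vox <- c(state$imm_vox, rec_cd8)
      state$imm_type <- c(state$imm_type, rep(1L, length(rec_cd8)))
      state$imm_kills <- c(state$imm_kills, integer(length(rec_cd8)))
      state$imm_count[rec_cd8] <- state$imm_count[rec_cd8] + 1L
    }
    rec_treg <- ep[runif(length(ep)) < cfg$treg_recruit_rate * dt]
    free <- immune_capacity(state$can_type, rec_treg) -
      state$imm_count[rec_treg]
    rec_treg <- rec_treg[free >= 1L]
    if (length(rec_treg)) {
      state$imm_vox <- c(state$imm_vox, rec_treg)
      state$imm_type <- c(state$imm_type, rep(4L, length(rec_treg)))
      state$imm_kills <- c(state$imm_kills, integer(length(rec_treg)))
      state$imm_count[rec_treg] <- state$imm_count[rec_treg] + 1L
    }
  }

  ## (4) immune random walk to Moore neighbors with free capacity
  n_imm <- length(state$imm_vox)
  if (n_imm) {
    mp <- moore_pairs(state$imm_vox, dims)
    free <- immune_capacity(state$can_type, mp$nbr) -
      state$imm_count[mp$nbr]
    src <- mp$src[free > 0L]; nbr <- mp$nbr[free > 0L]
    sel <- pick_one_per_src(src)
    mover <- src[sel]; target <- nbr[sel]
    # accept at most the free slots per target, random priority
    ord <- sample.int(length(target))
    mover <- mover[ord]; target <- target[ord]
    rank_in_target <- stats::ave(seq_along(target), target,
                                 FUN = seq_along)
    slots <- immune_capacity(state$can_type, target) -
      state$imm_count[target]
    acc <- rank_in_target <= slots
    mover <- mover[acc]; target <- target[acc]
    if (length(mover)) {
      old <- state$imm_vox[mover]
      # decrement origins and increment targets (voxels may repeat)
      dec <- tabulate(old, nbins = state$nvox)
      inc <- tabulate(target, nbins = state$nvox)
      state$imm_count <- state$imm_count - dec + inc
      state$imm_vox[mover] <- target
    }
  }

  ## (5) killing by effector/cytotoxic CD8+ cells
  conc <- drug_concentration(state$clock + dt, cfg)
  eff_block <- pd1_blockade_factor(conc, cfg)
  kill_sources <- NULL
  killers <- which(state$imm_type %in% c(1L, 2L))
  if (length(killers) && eff_block > 0) {
    kv <- state$imm_vox[killers]
    mp <- moore_pairs(kv, dims, include_self = TRUE)
    treg_count <- tabulate(state$imm_vox[state$imm_type == 4L],
                           nbins = state$nvox)
    treg_adj <- rowsum(treg_count[mp$nbr], mp$src) > 0
    has_cancer <- state$can_type[mp$nbr] > 0L
    csrc <- mp$src[has_cancer]; cnbr <- mp$nbr[has_cancer]
    sel <- pick_one_per_src(csrc)
    att_src <- csrc[sel]           # position into killers
    att_vic <- cnbr[sel]
    if (length(att_src)) {
      suppressed <- treg_adj[as.character(att_src), 1]
      p_kill <- cfg$base_kill_prob * eff_block *
        ifelse(suppressed, cfg$treg_suppression_factor, 1)
      hit <- runif(length(att_src)) < p_kill
      att_src <- att_src[hit]; att_vic <- att_vic[hit]
      # one death per cancer cell: random winner on collisions
      ord <- sample.int(length(att_vic))
      att_src <- att_src[ord]; att_vic <- att_vic[ord]
      keep <- !duplicated(att_vic)
      att_src <- att_src[keep]; att_vic <- att_vic[keep]
      if (length(att_vic)) {
        state$can_type[att_vic] <- 0L
        state$can_div[att_vic] <- 0L
        state$can_age[att_vic] <- 0
        kills <- length(att_vic)
        ki <- killers[att_src]
        state$imm_kills[ki] <- state$imm_kills[ki] + 1L
        ## (6) cytokine deposition at kill sites
        kill_sources <- att_vic
      }
    }
  }
  # CD8 state progression by cumulative kills
  cd8 <- state$imm_type %in% c(1L, 2L)
  exh <- cd8 & state$imm_kills >= cfg$exhaust_kill_threshold
  state$imm_type[exh] <- 3L
  cyt <- state$imm_type == 1L & state$imm_kills >= cfg$cyt_kill_threshold
  state$imm_type[cyt] <- 2L

  ## (7) cytokine diffusion-decay with kill-site sources
  src_il2 <- array(0, dims); src_ifng <- array(0, dims)
  if (!is.null(kill_sources)) {
    src_il2[kill_sources] <- cfg$il2_source
    src_ifng[kill_sources] <- cfg$ifng_source
  }
  state$il2 <- diffuse_field(state$il2, cfg$D_cytokine, cfg$cytokine_decay,
                             src_il2, dt, cfg$voxel_size)
  state$ifng <- diffuse_field(state$ifng, cfg$D_cytokine,
                              cfg$cytokine_decay, src_ifng, dt,
                              cfg$voxel_size)

  state$clock <- state$clock + dt
  state$events <- list(births = births, kills = kills,
                       senescent_deaths = sen_deaths)
  state
}

#' Convert a lattice state to a cell map
#'
#' Cells are positioned at their voxel centers (`(i - 0.5) * voxel_size`),
#' making the 20 um grid and the distance-based metrics interoperable.
#'
#' @param state A `lattice_state`.
#' @param cfg Its [sim_config()].
#' @return A 3-D [cell_map()] over the full box.
#' @export
state_to_cellmap <- function(state, cfg) {
  dims <- state$dims; vs <- cfg$voxel_size
  dec <- function(vox) {
    i <- (vox - 1L) %% dims[1] + 1L
    j <- ((vox - 1L) %/% dims[1]) %% dims[2] + 1L
    k <- (vox - 1L) %/% (dims[1] * dims[2]) + 1L
    data.frame(x = (i - 0.5) * vs, y = (j - 0.5) * vs, z = (k - 0.5) * vs)
  }
  cvox <- which(state$can_type > 0L)
  ctype <- c("CANCER_CSC", "CANCER_PROGENITOR",
             "CANCER_SENESCENT")[state$can_type[cvox]]
  itype <- c("T_EFF", "T_CYT", "T_EXH", "TREG")[state$imm_type]
  cells <- rbind(
    if (length(cvox)) data.frame(dec(cvox), cell_type = ctype),
    if (length(state$imm_vox)) data.frame(dec(state$imm_vox),
                                          cell_type = itype))
  if (is.null(cells))
    cells <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                        cell_type = character())
  cells <- data.frame(id = seq_len(nrow(cells)), cells)
  cell_map(cells, bounds(c(0, dims[1] * vs), c(0, dims[2] * vs),
                         c(0, dims[3] * vs)))
}

# ---- full runs --------------------------------------------------------

#' Run the simulator over replicates
#'
#' Runs `cfg$n_replicates` independent stochastic replicates, each seeded
#' deterministically with `random_seed + replicate`, over the full
#' duration. Per step, the per-type cell counts and the step's event
#' tallies are recorded; at each sampling time the 3-D state can be
#' delivered to a callback (e.g. to slice, crop and score it on the fly)
#' and/or stored as a snapshot.
#'
#' @param cfg A [sim_config()].
#' @param sample_interval Days between samples (default 3); `NULL`
#'   disables sampling.
#' @param on_sample Optional `function(cellmap, time, replicate)` called
#'   at every sampling time with the full 3-D [cell_map()].
#' @param keep_snapshots If `TRUE`, store the sampled cell maps in each
#'   trajectory (memory-heavy; default `FALSE`).
#' @param check_state If `TRUE`, run [validate_state()] after every step.
#' @return A `sim_result`: list of per-replicate trajectories (each with
#'   a `counts` data.frame and optionally `snapshots`), plus a `summary`
#'   data.frame with the replicate mean and SD of the relative change in
#'   cancer-cell number over time.
#' @export
run_simulation <- function(cfg, sample_interval = 3, on_sample = NULL,
                           keep_snapshots = FALSE, check_state = FALSE) {
  n_steps <- round(cfg$duration / cfg$time_step)
  sample_steps <- if (is.null(sample_interval)) integer() else {
    by <- max(1L, round(sample_interval / cfg$time_step))
    seq(0L, n_steps, by = by)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  trajectories <- vector("list", cfg$n_replicates)
  for (rep_i in seq_len(cfg$n_replicates)) {
    set.seed(cfg$random_seed + rep_i)
    state <- init_state(cfg)
    counts <- matrix(0L, nrow = n_steps + 1L, ncol = 12L)
    colnames(counts) <- c("step", "n_csc", "n_prog", "n_senescent",
                          "n_cancer", "n_eff", "n_cyt", "n_exh", "n_treg",
                          "births", "kills", "senescent_deaths")
    record <- function(s, st) {
      c(s, sum(st$can_type == 1L), sum(st$can_type == 2L),
        sum(st$can_type == 3L), sum(st$can_type > 0L),
        sum(st$imm_type == 1L), sum(st$imm_type == 2L),
        sum(st$imm_type == 3L), sum(st$imm_type == 4L),
        st$events$births, st$events$kills, st$events$senescent_deaths)
    }
    counts[1L, ] <- record(0L, state)
    snapshots <- list()
    deliver <- function(step_no) {
      if (!(step_no %in% sample_steps)) return()
      cm <- state_to_cellmap(state, cfg)
      t <- step_no * cfg$time_step
      if (!is.null(on_sample)) on_sample(cm, t, rep_i)
      if (keep_snapshots) snapshots[[as.character(t)]] <<- cm
    }
    deliver(0L)
    for (s in seq_len(n_steps)) {
      state <- advance(state, cfg)
      if (check_state) validate_state(state)
      counts[s + 1L, ] <- record(s, state)
      deliver(s)
    }
    counts <- as.data.frame(counts)
    counts$time <- counts$step * cfg$time_step
    n0 <- counts$n_cancer[1]
    counts$relative_change <- (counts$n_cancer - n0) / n0
    trajectories[[rep_i]] <- list(replicate = rep_i, counts = counts,
                                  snapshots = snapshots)
  }
  rel <- vapply(trajectories, function(tr) tr$counts$relative_change,
                numeric(n_steps + 1L))
  summary <- data.frame(
    time = trajectories[[1]]$counts$time,
    mean_relative_change = rowMeans(rel),
    sd_relative_change = apply(rel, 1L, stats::sd),
    mean_n_cancer = rowMeans(vapply(trajectories,
                                    function(tr) tr$counts$n_cancer,
                                    numeric(n_steps + 1L))))
  structure(list(trajectories = trajectories, summary = summary,
                 config = cfg), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  fin <- utils::tail(x$summary, 1L)
  cat(sprintf(
    "<sim_result> %d replicate(s), %g days | final cancer count %.1f (rel. change %+.2f +/- %.2f)\n",
    length(x$trajectories), max(x$summary$time), fin$mean_n_cancer,
    fin$mean_relative_change, fin$sd_relative_change))
  invisible(x)
}
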