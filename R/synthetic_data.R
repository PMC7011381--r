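#' Derive a reproducible sub-seed
#'
#' Counter-based seed splitting: every sample (or stage) of a simulation
#' gets its own RNG stream derived from the global seed and an index, so
#' changing the order or the subset of samples simulated never changes an
#' individual sample's draw.
#'
#' @param seed global integer seed.
#' @param index nonnegative integer counter.
#' @return An integer seed in 1..2^31-2.
#' @keywords internal
seed_stream <- function(seed, index) {
  # affine hash mod the Mersenne prime 2^31 - 1; all products < 2^53
  h <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 16807 + 1
  as.integer(h %% 2147483646) + 1L
}

#' Build a source (meta)community pool
#'
#' The source pool is the metacommunity of the neutral model: the fixed
#' taxon proportions that immigrants are drawn from. Two species-abundance
#' distributions are offered: lognormal (realistic, long-tailed; `sigma`
#' controls unevenness) and flat Dirichlet.
#'
#' @param S number of taxa (>= 2).
#' @param sad `"lognormal"` or `"dirichlet_uniform"`.
#' @param sad_params list; `sigma` (lognormal sd on the log scale,
#'   default 2) or `alpha` (Dirichlet concentration, default 1).
#' @param seed integer seed.
#' @return A list of class `source_pool` with `taxon_ids` and strictly
#'   positive `q` summing to 1.
#' @export
make_source_pool <- function(S, sad = c("lognormal", "dirichlet_uniform"),
                             sad_params = list(), seed = 1L) {
  if (S < 2) stop("S must be >= 2")
  sad <- match.arg(sad)
  set.seed(seed_stream(seed, 0L))
  if (sad == "lognormal") {
    sigma <- if (is.null(sad_params$sigma)) 2 else sad_params$sigma
    x <- stats::rlnorm(S, meanlog = 0, sdlog = sigma)
  } else {
    alpha <- if (is.null(sad_params$alpha)) 1 else sad_params$alpha
    x <- stats::rgamma(S, shape = alpha, rate = 1)
  }
  x <- pmax(x, .Machine$double.xmin)
  structure(list(taxon_ids = paste0("OTU", seq_len(S)), q = x / sum(x)),
            class = "source_pool")
}

#' Simulation configuration
#'
#' @param S number of taxa (must match the pool it is used with).
#' @param n_samples number of independent local communities.
#' @param N_local local community size in individuals (>= 10).
#' @param m migration probability in (0, 1]: chance that a death is
#'   replaced by an immigrant from the source pool rather than by local
#'   reproduction.
#' @param depth sequencing depth: reads drawn per sample (multinomial).
#' @param selection named numeric vector of fitness multipliers w by taxon
#'   id; taxa absent from the map have w = 1 (neutral).
#' @param mode `"stationary"` (Dirichlet approximation of the neutral
#'   stationary state; only valid with no selection) or `"dynamic"`
#'   (explicit death-replacement events).
#' @param seed integer seed.
#' @param burnin_factor dynamic-mode burn-in, in units of N_local events.
#' @param q_init optional founding composition (proportions over the pool
#'   taxa) for dynamic mode; default the source pool itself. Models early
#'   colonization that differs from ongoing immigration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(S, n_samples, N_local = 1000, m = 0.3, depth = 2000,
                       selection = numeric(0),
                       mode = c("stationary", "dynamic"), seed = 1L,
                       burnin_factor = 10, q_init = NULL) {
  mode <- match.arg(mode)
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (N_local < 10) stop("N_local must be >= 10")
  if (depth < 1) stop("depth must be >= 1")
  if (length(selection) && (is.null(names(selection)) || any(selection <= 0)))
    stop("selection must be a named vector of positive fitness multipliers")
  structure(list(S = as.integer(S), n_samples = as.integer(n_samples),
                 N_local = as.integer(N_local), m = m,
                 depth = as.integer(depth), selection = selection,
                 mode = mode, seed = as.integer(seed),
                 burnin_factor = burnin_factor, q_init = q_init),
            class = "sim_config")
}

#' Mark taxa as under selection
#'
#' Returns a copy of the configuration in which the given taxa reproduce
#' with fitness multiplier `w` in dynamic-mode simulation (selection acts
#' on reproduction, not on immigration). `w = 1` is the neutral identity
#' and leaves the configuration unchanged; `w > 1` models a host-selected,
#' over-represented taxon, `w < 1` an actively excluded one.
#'
#' @param cfg a [sim_config()].
#' @param taxa character taxon ids.
#' @param w positive fitness multiplier.
#' @return The modified [sim_config()].
#' @export
inject_selection <- function(cfg, taxa, w) {
  stopifnot(inherits(cfg, "sim_config"))
  if (w <= 0) stop("w must be > 0")
  if (w == 1) return(cfg)
  sel <- cfg$selection
  sel[taxa] <- w
  cfg$selection <- sel
  if (cfg$mode == "stationary") cfg$mode <- "dynamic"
  cfg
}

selection_weights <- function(pool, selection) {
  w <- rep(1, length(pool$taxon_ids))
  if (length(selection)) {
    idx <- match(names(selection), pool$taxon_ids)
    if (anyNA(idx))
      stop("unknown taxon id(s) in selection map: ",
           paste(names(selection)[is.na(idx)], collapse = ", "))
    w[idx] <- selection
  }
  w
}

#' Simulate neutral (or selected) local communities
#'
#' Assembles `n_samples` independent local communities from a source pool
#' and sequences each to the configured depth with a multinomial draw.
#' Stationary mode draws local proportions from Dirichlet(I q) with
#' I = m (N_local - 1) / (1 - m), the stationary approximation of the
#' neutral birth-death-immigration process (I capped at 1e6 as m -> 1);
#' it is only valid with no selection. Dynamic mode runs the explicit
#' death-replacement process (`burnin_factor * N_local` events per
#' sample) and supports per-taxon fitness multipliers.
#'
#' @param pool a [make_source_pool()] pool.
#' @param cfg a [sim_config()]; `cfg$S` must equal the pool size.
#' @return A [count_table()] (samples x taxa); every row sums to
#'   `cfg$depth`.
#' @export
simulate_neutral_community <- function(pool, cfg) {
  stopifnot(inherits(pool, "source_pool"), inherits(cfg, "sim_config"))
  S <- length(pool$taxon_ids)
  if (cfg$S != S) stop("cfg$S does not match pool size")
  w <- selection_weights(pool, cfg$selection)
  if (cfg$mode == "stationary" && any(w != 1))
    stop("stationary mode is only valid without selection (all w = 1)")
  q <- pool$q
  counts <- matrix(0L, cfg$n_samples, S)
  if (cfg$mode == "stationary") {
    I <- min(cfg$m * (cfg$N_local - 1) / max(1 - cfg$m, .Machine$double.eps),
             1e6)
    for (k in seq_len(cfg$n_samples)) {
      set.seed(seed_stream(cfg$seed, k))
      g <- stats::rgamma(S, shape = I * q, rate = 1)
      props <- if (sum(g) > 0) g / sum(g) else q
      counts[k, ] <- stats::rmultinom(1, cfg$depth, props)[, 1]
    }
  } else {
    n_events <- as.integer(round(cfg$burnin_factor * cfg$N_local))
    for (k in seq_len(cfg$n_samples)) {
      set.seed(seed_stream(cfg$seed, k))
      local <- moran_community(q, w, cfg$m, cfg$N_local, n_events,
                               cfg$q_init)
      counts[k, ] <- stats::rmultinom(1, cfg$depth, local / cfg$N_local)[, 1]
    }
  }
  count_table(counts, sample_ids = paste0("S", seq_len(cfg$n_samples)),
              otu_ids = pool$taxon_ids)
}

#' Exposure/recovery preset emulating the perch cadmium study design
#'
#' Encodes the factorial design of the study the package is modeled on:
#' 3 exposure regimes x 3 habitats x 8 tanks x 7 timepoints x replicates,
#' with an exposure phase (T0 to T3) and a recovery phase (TR1 to T5).
#' Selection severity is expressed on a 0..1 scale per (treatment,
#' habitat, timepoint); the applied fitness multiplier is
#' `w_max ^ severity`. CC ramps to full severity at T3 and relaxes fully
#' by T5 in gut and water but retains a residual in skin (the alternative
#' stable state); CV also peaks at T3 but relaxes more slowly and retains
#' residual severity at T5. A small set of host-selected
#' (Mycoplasma-like) strains colonizes each fish with probability
#' `host_prevalence`; in a colonized fish the strain is seeded early and
#' held by host selection at a stable community share (`host_dominance`
#' jointly with the other colonizing strains), while in non-colonized
#' fish it is effectively absent. The result is a taxon that is abundant
#' on average but patchily occurring — the occupancy pattern that never
#' fits the neutral expectation, under every regime and timepoint.
#'
#' @param S taxa in the shared pool.
#' @param tanks,replicates design width; defaults 8 tanks x 3 replicates.
#' @param habitats,timepoints subsets of the full design, for scaled runs.
#' @param n_selected cadmium-susceptible resident taxa per habitat.
#' @param cd_w their fitness multiplier at full exposure severity
#'   (< 1: cadmium suppresses susceptible residents; the applied
#'   multiplier is `cd_w ^ severity`).
#' @param n_host_selected host-selected strains (skin/gut only).
#' @param host_dominance stable community share of the host-selected
#'   block in a colonized fish; the required fitness multiplier is
#'   derived per habitat from the selection-immigration balance,
#'   w = (1 - p*) / (1 - p* - m).
#' @param host_prevalence probability that a fish is colonized by each
#'   host-selected strain.
#' @param m per-habitat migration rates (named vector).
#' @param N_local,depth local community size and sequencing depth.
#' @return A preset list consumed by [simulate_experiment()].
#' @export
perch_recovery_preset <- function(S = 300, tanks = 8, replicates = 3,
                                  habitats = HABITAT_LEVELS,
                                  timepoints = TIMEPOINT_LEVELS,
                                  n_selected = 40, cd_w = 0.01,
                                  n_host_selected = 2,
                                  host_dominance = 0.25,
                                  host_prevalence = 0.7,
                                  m = c(water = 0.5, skin = 0.2, gut = 0.1),
                                  N_local = 1000, depth = 2000) {
  if (any(m[c("skin", "gut")] >= 1 - host_dominance, na.rm = TRUE))
    stop("host_dominance too large for the host migration rates")
  sev <- rbind(
    Ctrl = c(T0 = 0, T3 = 0,  TR1 = 0,   TR2 = 0,    TR3 = 0,   TR4 = 0,    T5 = 0),
    CC   = c(T0 = 0, T3 = 1,  TR1 = 0.6, TR2 = 0.4,  TR3 = 0.2, TR4 = 0.1,  T5 = 0),
    CV   = c(T0 = 0, T3 = 1,  TR1 = 0.8, TR2 = 0.65, TR3 = 0.5, TR4 = 0.35, T5 = 0.2))
  # residual severity through the recovery phase: skin (and, less so,
  # water) settles in an alternative stable state instead of returning to
  # the control configuration; the gut relaxes fully under CC and only
  # partially under CV
  residual <- rbind(Ctrl = c(water = 0,    skin = 0,   gut = 0),
                    CC   = c(water = 0.35, skin = 0.6, gut = 0),
                    CV   = c(water = 0.45, skin = 0.7, gut = 0.5))
  list(S = S, tanks = tanks, replicates = replicates,
       habitats = match.arg(habitats, HABITAT_LEVELS, several.ok = TRUE),
       timepoints = match.arg(timepoints, TIMEPOINT_LEVELS, several.ok = TRUE),
       n_selected = n_selected, cd_w = cd_w,
       n_host_selected = n_host_selected, host_dominance = host_dominance,
       host_prevalence = host_prevalence,
       m = m, N_local = N_local, depth = depth,
       severity = sev, residual = residual)
}

preset_severity <- function(preset, treatment, habitat, timepoint) {
  s <- preset$severity[treatment, timepoint]
  recovery <- c("TR1", "TR2", "TR3", "TR4", "T5")
  if (timepoint %in% recovery)
    s <- max(s, preset$residual[treatment, habitat])
  s
}

#' Simulate the full factorial exposure-recovery experiment
#'
#' Generates one community per (treatment x habitat x tank x timepoint x
#' replicate) cell by the dynamic neutral/selective process, each habitat
#' with its own source pool and migration rate, plus a shared Kingman
#' coalescent tree over all taxa (for UniFrac) and a ground-truth ledger.
#'
#' @param preset a [perch_recovery_preset()].
#' @param seed global integer seed; every sample gets a derived stream.
#' @return A list: `counts` ([count_table()]), `metadata`
#'   ([sample_metadata()]), `tree` (phylo), `truth` (list with per-habitat
#'   m, selected-taxon table, severity schedule).
#' @export
simulate_experiment <- function(preset = perch_recovery_preset(), seed = 1L) {
  habitats <- preset$habitats
  timepoints <- preset$timepoints
  design <- expand.grid(replicate = seq_len(preset$replicates),
                        tank = seq_len(preset$tanks),
                        timepoint = timepoints,
                        treatment = TREATMENT_LEVELS,
                        habitat = habitats,
                        stringsAsFactors = FALSE)
  otu_ids <- paste0("OTU", seq_len(preset$S))
  pools <- lapply(seq_along(habitats), function(h)
    make_source_pool(preset$S, sad = "lognormal",
                     sad_params = list(sigma = 2),
                     seed = seed_stream(seed, 1000000 + h)))
  names(pools) <- habitats

  # ground-truth selected taxa: cadmium-responsive per habitat, plus
  # host-selected taxa shared by skin and gut
  sel_tab <- data.frame(otu_id = character(0), habitat = character(0),
                        type = character(0), w = numeric(0),
                        stringsAsFactors = FALSE)
  if (preset$n_selected > 0) {
    # cadmium-susceptible taxa are residents: drawn from the abundant half
    # of each habitat's source pool (a taxon must be established in the
    # community to be suppressed by the exposure)
    sel_tab <- do.call(rbind, lapply(seq_along(habitats), function(h) {
      set.seed(seed_stream(seed, 2000000 + h))
      res <- order(pools[[h]]$q, decreasing = TRUE)[seq_len(preset$S %/% 2)]
      idx <- sample(res, preset$n_selected)
      data.frame(otu_id = otu_ids[idx], habitat = habitats[h],
                 type = "cadmium", w = preset$cd_w,
                 stringsAsFactors = FALSE)
    }))
  }
  # host-selected strains: rare in the source pool (they persist by host
  # adaptation, not dispersal); the fitness multiplier maintaining a
  # stable share p* against immigration is w = (1 - p*) / (1 - p* - m)
  host_idx <- integer(0)
  host_w <- c(skin = NA_real_, gut = NA_real_)
  if (preset$n_host_selected > 0 && any(habitats %in% c("skin", "gut"))) {
    set.seed(seed_stream(seed, 3000000))
    host_habs <- intersect(c("skin", "gut"), habitats)
    rare <- Reduce(intersect, lapply(host_habs, function(h)
      order(pools[[h]]$q)[seq_len(preset$S %/% 2)]))
    if (length(rare) < preset$n_host_selected)
      rare <- order(pools[[host_habs[1]]]$q)[seq_len(preset$S %/% 2)]
    host_idx <- sample(rare, preset$n_host_selected)
    for (h in intersect(c("skin", "gut"), habitats)) {
      host_w[h] <- (1 - preset$host_dominance) /
        (1 - preset$host_dominance - preset$m[[h]])
      sel_tab <- rbind(sel_tab,
                       data.frame(otu_id = otu_ids[host_idx], habitat = h,
                                  type = "host", w = unname(host_w[h]),
                                  stringsAsFactors = FALSE,
                                  row.names = NULL))
    }
  }

  n <- nrow(design)
  counts <- matrix(0L, n, preset$S)
  ids <- character(n)
  for (r in seq_len(n)) {
    hab <- design$habitat[r]; trt <- design$treatment[r]
    tp <- design$timepoint[r]
    ids[r] <- sprintf("%s_%s_%s_tk%d_r%d", hab, trt, tp,
                      design$tank[r], design$replicate[r])
    sel <- numeric(0)
    pool_r <- pools[[hab]]
    s <- preset_severity(preset, trt, hab, tp)
    if (s > 0) {
      cad <- sel_tab$otu_id[sel_tab$habitat == hab & sel_tab$type == "cadmium"]
      sel[cad] <- preset$cd_w^s
      if (hab == "water") {
        # the water column's source inflow is itself cadmium-exposed, so
        # susceptible taxa are also depleted among immigrants; host
        # habitats keep an unshifted source (ambient water and feed)
        q_mod <- pool_r$q
        q_mod[match(cad, pool_r$taxon_ids)] <-
          q_mod[match(cad, pool_r$taxon_ids)] * preset$cd_w^s
        pool_r <- structure(list(taxon_ids = pool_r$taxon_ids,
                                 q = q_mod / sum(q_mod)),
                            class = "source_pool")
      }
    }
    q_init <- NULL
    if (hab %in% c("skin", "gut") && length(host_idx)) {
      set.seed(seed_stream(seed, 5000000 + r))
      colonized <- host_idx[stats::runif(length(host_idx)) <
                              preset$host_prevalence]
      if (length(colonized)) {
        sel[otu_ids[colonized]] <- host_w[hab]
        # founding composition: colonizing strains start at their stable
        # block share; the rest of the community is founded from the pool
        q_init <- pools[[hab]]$q * (1 - preset$host_dominance)
        q_init[colonized] <- q_init[colonized] +
          preset$host_dominance / length(colonized)
      }
    }
    cfg <- sim_config(preset$S, n_samples = 1L, N_local = preset$N_local,
                      m = unname(preset$m[hab]), depth = preset$depth,
                      selection = sel, mode = "dynamic",
                      seed = seed_stream(seed, r), q_init = q_init)
    counts[r, ] <- unclass(simulate_neutral_community(pool_r, cfg))[1, ]
  }
  tab <- count_table(counts, sample_ids = ids, otu_ids = otu_ids)
  meta <- sample_metadata(data.frame(sample_id = ids,
                                     treatment = design$treatment,
                                     habitat = design$habitat,
                                     timepoint = design$timepoint,
                                     tank = design$tank,
                                     replicate = design$replicate,
                                     stringsAsFactors = FALSE))
  set.seed(seed_stream(seed, 4000000))
  tree <- ape::rcoal(preset$S, tip.label = otu_ids)
  list(counts = tab, metadata = meta, tree = tree,
       truth = list(m = preset$m, selected = sel_tab,
                    severity = preset$severity, residual = preset$residual,
                    pools = pools))
}
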