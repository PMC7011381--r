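#' Analysis configuration
#'
#' Bundles the inputs and tuning parameters of the full recovery
#' analysis. Inputs may be given as file paths (TSV counts/metadata,
#' Newick tree) or as in-memory objects from the simulator.
#'
#' @param counts path or [count_table()].
#' @param metadata path or [sample_metadata()].
#' @param tree path or `phylo`.
#' @param out_dir directory for report TSVs and the run manifest; NULL
#'   keeps everything in memory.
#' @param n_perm permutations for all distance-based tests.
#' @param alpha significance level used for the recovered flag.
#' @param gunifrac_alpha GUniFrac abundance exponent.
#' @param rho_min named per-habitat network correlation threshold.
#' @param fdr network edge FDR level.
#' @param d,ci_level,bootstrap neutral-model parameters.
#' @param seed global seed; all stage seeds are derived streams.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(counts, metadata, tree, out_dir = NULL,
                            n_perm = 999, alpha = 0.05,
                            gunifrac_alpha = 0.5,
                            rho_min = c(water = 0.5, skin = 0.3, gut = 0.3),
                            fdr = 0.05, d = 1L, ci_level = 0.95,
                            bootstrap = 0L, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(counts = counts, metadata = metadata, tree = tree,
                 out_dir = out_dir, n_perm = n_perm, alpha = alpha,
                 gunifrac_alpha = gunifrac_alpha, rho_min = rho_min,
                 fdr = fdr, d = d, ci_level = ci_level,
                 bootstrap = bootstrap, seed = as.integer(seed)),
            class = "analysis_config")
}

load_input <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full recovery analysis
#'
#' Composes every stage over the factorial design: per-sample alpha
#' diversity; per-habitat GUniFrac distances with all-groups and
#' pairwise PERMANOVA, dispersion-homogeneity and MRPP tests per
#' timepoint (pairwise PERMANOVA p Benjamini-Hochberg-adjusted within
#' each timepoint); the Sloan neutral-model fit and neutral/above/below
#' percentages per (habitat, treatment, timepoint) stratum; per-cell
#' sample-correlation networks with centrality summaries; terminal-time
#' differential abundance against control; and the distance-to-control
#' recovery trajectory. Deterministic given `cfg$seed`; when
#' `cfg$out_dir` is set all report tables plus a JSON manifest are
#' written there.
#'
#' @param cfg an [analysis_config()].
#' @return A list of class `recovery_report` with elements `alpha`,
#'   `beta`, `ncm`, `centrality`, `diff_abund`, `trajectory`, `dist`
#'   (per-habitat [dist_matrix()]), and `warnings`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  counts <- load_input(cfg$counts, read_count_table)
  metadata <- load_input(cfg$metadata, read_metadata)
  tree <- load_input(cfg$tree, read_newick)
  meta <- align_metadata(metadata, counts)
  habitats <- levels(droplevels(meta$habitat))
  notes <- character(0)

  alpha_tab <- cbind(alpha_diversity(counts),
                     meta[c("treatment", "habitat", "timepoint", "tank",
                            "replicate")])

  beta_rows <- list()
  ncm_fits <- list()
  dms <- list()
  cent_tabs <- list()
  diff_tabs <- list()
  stage_seed <- 0L
  for (hab in habitats) {
    sel <- meta$habitat == hab
    sub <- count_table(unclass(counts)[sel, , drop = FALSE])
    msub <- meta[sel, , drop = FALSE]
    dm <- gunifrac(sub, tree, alpha = cfg$gunifrac_alpha, prune = TRUE)
    dms[[hab]] <- dm
    tps <- levels(droplevels(msub$timepoint))
    for (tp in tps) {
      tsel <- msub$timepoint == tp
      ids <- msub$sample_id[tsel]
      dmt <- subset_dist(dm, ids)
      g <- droplevels(msub$treatment[tsel])
      stage_seed <- stage_seed + 1L
      row_all <- NULL
      if (nlevels(g) >= 2 && all(table(g) >= 2)) {
        pa <- permanova(dmt, g, n_perm = cfg$n_perm,
                        seed = seed_stream(cfg$seed, stage_seed))
        row_all <- data.frame(habitat = hab, timepoint = tp,
                              comparison = "All groups",
                              permanova_F = pa$statistic,
                              permanova_p = pa$p_value,
                              permanova_p_bh = NA_real_,
                              betadisper_p = NA_real_, mrpp_p = NA_real_,
                              mrpp_A = NA_real_, stringsAsFactors = FALSE)
      }
      pair_rows <- list()
      levs <- levels(g)
      if (length(levs) >= 2) {
        pairs <- utils::combn(sort(levs, method = "radix"), 2,
                              simplify = FALSE)
        for (pr in pairs) {
          psel <- g %in% pr
          if (sum(psel) < 4 || any(table(droplevels(g[psel])) < 2)) next
          dmp <- subset_dist(dmt, ids[psel])
          gp <- droplevels(g[psel])
          stage_seed <- stage_seed + 1L
          s <- seed_stream(cfg$seed, stage_seed)
          pa <- permanova(dmp, gp, n_perm = cfg$n_perm, seed = s)
          bd <- betadisper(dmp, gp, n_perm = cfg$n_perm, seed = s)
          mr <- mrpp(dmp, gp, n_perm = cfg$n_perm, seed = s)
          pair_rows[[paste(pr, collapse = "-")]] <-
            data.frame(habitat = hab, timepoint = tp,
                       comparison = paste(pr, collapse = "-"),
                       permanova_F = pa$statistic, permanova_p = pa$p_value,
                       permanova_p_bh = NA_real_,
                       betadisper_p = bd$p_value, mrpp_p = mr$p_value,
                       mrpp_A = mr$A, stringsAsFactors = FALSE)
        }
      }
      if (length(pair_rows)) {
        pr_tab <- do.call(rbind, pair_rows)
        pr_tab$permanova_p_bh <- bh_adjust(pr_tab$permanova_p)
        beta_rows[[paste(hab, tp)]] <- rbind(row_all, pr_tab)
      } else if (!is.null(row_all)) {
        beta_rows[[paste(hab, tp)]] <- row_all
      }
      # neutral-model fit per stratum
      for (trt in levels(g)) {
        ssel <- tsel & msub$treatment == trt
        nm <- sprintf("%s.%s.%s", hab, trt, tp)
        ncm_fits[[nm]] <- withCallingHandlers(
          tryCatch(
            fit_ncm(count_table(unclass(sub)[ssel, , drop = FALSE]),
                    d = cfg$d, ci_level = cfg$ci_level,
                    bootstrap = cfg$bootstrap, seed = cfg$seed),
            error = function(e) {
              notes <<- c(notes, sprintf("NCM skipped for %s: %s", nm,
                                         conditionMessage(e)))
              NULL
            }),
          warning = function(w) {
            notes <<- c(notes, sprintf("NCM %s: %s", nm,
                                       conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
      }
    }
    # one joint network per timepoint (all treatments together, as in the
    # study's network figures), centrality compared by treatment inside it
    rm_h <- if (hab %in% names(cfg$rho_min)) cfg$rho_min[[hab]] else 0.5
    ct_rows <- list()
    for (tp in tps) {
      csel <- msub$timepoint == tp
      if (sum(csel) < 3) next
      net <- tryCatch(
        build_network(count_table(unclass(sub)[csel, , drop = FALSE]),
                      rho_min = rm_h, fdr_alpha = cfg$fdr,
                      metadata = msub),
        error = function(e) NULL)
      if (is.null(net)) next
      cg <- centrality_by_group(net)
      ct_rows[[tp]] <- cbind(habitat = hab, timepoint = tp,
                             n_edges = nrow(net$edges), cg,
                             stringsAsFactors = FALSE)
    }
    cent_tabs[[hab]] <- do.call(rbind, ct_rows)
    # terminal-time differential abundance vs control
    term <- tps[length(tps)]
    for (trt in setdiff(levels(droplevels(msub$treatment)), "Ctrl")) {
      dsel <- msub$timepoint == term & msub$treatment %in% c("Ctrl", trt)
      if (length(unique(msub$treatment[dsel])) == 2) {
        da <- tryCatch(
          differential_abundance(count_table(unclass(sub)[dsel, , drop = FALSE]),
                                 msub, "treatment",
                                 contrast = c("Ctrl", trt)),
          error = function(e) NULL)
        if (!is.null(da))
          diff_tabs[[paste(hab, trt, term, sep = ".")]] <-
            cbind(habitat = hab, contrast = paste0("Ctrl-", trt),
                  timepoint = term, da, stringsAsFactors = FALSE)
      }
    }
  }
  beta_tab <- do.call(rbind, beta_rows)
  rownames(beta_tab) <- NULL
  report <- structure(list(alpha = alpha_tab, beta = beta_tab,
                           ncm = neutral_fraction_summary(ncm_fits),
                           ncm_fits = ncm_fits,
                           centrality = do.call(rbind, cent_tabs),
                           diff_abund = do.call(rbind, diff_tabs),
                           dist = dms, metadata = meta,
                           config = cfg, warnings = notes),
                      class = "recovery_report")
  report$trajectory <- do.call(rbind, lapply(habitats, function(h)
    recovery_trajectory(report, h)))
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Distance-to-control recovery trajectory
#'
#' For one habitat: the mean GUniFrac distance between control and each
#' treatment's samples at every timepoint (with the within-control mean
#' distance as the convergence baseline), plus a `recovered` flag set
#' when the terminal-timepoint pairwise PERMANOVA contrast against
#' control has adjusted p above the configured alpha — i.e. the
#' community is statistically indistinguishable from control at the end
#' of the recovery phase.
#'
#' @param report a `recovery_report` from [run_full_analysis()].
#' @param habitat habitat to extract.
#' @return data.frame: habitat, treatment, timepoint, dist_to_ctrl,
#'   within_ctrl_dist, recovered (at terminal timepoint rows; NA before).
#' @export
recovery_trajectory <- function(report, habitat) {
  if (!habitat %in% names(report$dist))
    stop("habitat not in report: ", habitat)
  dm <- report$dist[[habitat]]
  meta <- report$metadata[report$metadata$habitat == habitat, , drop = FALSE]
  tps <- levels(droplevels(meta$timepoint))
  term <- tps[length(tps)]
  treatments <- setdiff(levels(droplevels(meta$treatment)), "Ctrl")
  rows <- list()
  for (trt in treatments) {
    for (tp in tps) {
      ctrl_ids <- meta$sample_id[meta$treatment == "Ctrl" &
                                   meta$timepoint == tp]
      trt_ids <- meta$sample_id[meta$treatment == trt &
                                  meta$timepoint == tp]
      if (!length(ctrl_ids) || !length(trt_ids)) next
      between <- mean(unclass(dm)[ctrl_ids, trt_ids])
      wd <- unclass(dm)[ctrl_ids, ctrl_ids]
      within <- if (length(ctrl_ids) > 1)
        sum(wd) / (length(ctrl_ids) * (length(ctrl_ids) - 1)) else NA_real_
      recovered <- NA
      if (tp == term && !is.null(report$beta)) {
        hit <- report$beta$habitat == habitat &
          report$beta$timepoint == term &
          report$beta$comparison %in% paste(sort(c("Ctrl", trt),
                                                 method = "radix"),
                                            collapse = "-")
        if (any(hit))
          recovered <- report$beta$permanova_p_bh[hit][1] >
            report$config$alpha
      }
      rows[[paste(trt, tp)]] <- data.frame(habitat = habitat,
                                           treatment = trt, timepoint = tp,
                                           dist_to_ctrl = between,
                                           within_ctrl_dist = within,
                                           recovered = recovered,
                                           stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write report tables and a run manifest
#'
#' @param report a `recovery_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wt(report$alpha, "alpha_diversity.tsv")
  wt(report$beta, "beta_divergence.tsv")
  wt(report$ncm, "ncm_summary.tsv")
  wt(report$centrality, "network_centrality.tsv")
  wt(report$diff_abund, "differential_abundance.tsv")
  wt(report$trajectory, "recovery_trajectory.tsv")
  cfg <- report$config
  manifest <- list(
    package = "recoverymics",
    version = as.character(utils::packageVersion("recoverymics")),
    seed = cfg$seed, n_perm = cfg$n_perm, alpha = cfg$alpha,
    gunifrac_alpha = cfg$gunifrac_alpha,
    rho_min = as.list(cfg$rho_min), fdr = cfg$fdr, d = cfg$d,
    ci_level = cfg$ci_level, bootstrap = cfg$bootstrap,
    n_samples = nrow(report$alpha),
    habitats = names(report$dist),
    warnings = report$warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
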