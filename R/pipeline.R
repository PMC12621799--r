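#' Build and validate a pipeline configuration
#'
#' One configuration drives the whole synthetic study: which stages run,
#' their parameters, and a single root seed from which each stage derives
#' its own seed (`root_seed + a fixed per-stage offset`, so stages are
#' independently reproducible). Unknown keys at either level are rejected
#' rather than silently ignored.
#'
#' @param config named list (or path to a YAML file) with any of the
#'   sections `stages`, `masks`, `morphometrics`, `omics`, `rppa`, `plsr`,
#'   `network`, `seed`; omitted entries take the defaults below.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    seed = 1L,
    stages = list(masks = TRUE, morphometrics = TRUE, omics = TRUE,
                  rppa = TRUE, plsr = TRUE, network = TRUE),
    masks = list(n_per_well = 20L, n_wells = 2L, size_px = 25,
                 control_aspect = 1.2, treated_aspect = 2.0,
                 pixel_size = 0.65),
    morphometrics = list(min_intensity = 0, max_pct_touching = 0.5),
    omics = list(n_probes = 172L, n_outputs = 15L, n_latent = 2L,
                 noise_sigma = 0.05),
    rppa = list(fraction = 0.2, control_ligand = "serumfree",
                n_replicates = 2L),
    plsr = list(n_components = 2L, k = 4L, phenotype = "feret_elongation"),
    network = list(t_end = 20, perturb_factor = 0)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- defaults
  for (sec in names(config)) {
    if (sec == "seed") {
      out$seed <- as.integer(config$seed)
      next
    }
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  structure(out, class = "pipeline_config")
}

# Per-stage seeds derived from the root seed; offsets are arbitrary small
# constants, kept stable for reproducibility.
stage_seed <- function(config, stage) {
  offsets <- c(masks = 101L, omics = 211L, rppa = 307L, plsr = 401L,
               phenotypes = 503L)
  as.integer(config$seed) + offsets[[stage]]
}

write_stage_csv <- function(df, dir, name, written) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(written, path)
}

#' Run the end-to-end synthetic study
#'
#' Executes the enabled stages in dependency order — synthetic masks,
#' morphometric features and well profiles, synthetic omics blocks, RPPA
#' preprocessing (raw -> normalized -> log2 fold-change -> top responders
#' -> Venn overlaps), PLSR fitting with leave-one-out Q2, clustering and
#' alignment, and the Nrg1 network simulation with PI3K/p38 knockout
#' panel. All tables land in `out_dir`; the resolved configuration is
#' echoed there as YAML for provenance, and the returned manifest lists
#' every produced file with its MD5 content hash (a rerun with the same
#' configuration reproduces identical hashes). A stage failure aborts the
#' run naming the stage, after renaming that stage's partial outputs with
#' a `.partial` suffix.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param out_dir output directory, created if needed.
#' @return data.frame manifest with columns `file`, `md5`, invisibly
#'   written to `manifest.csv` as well.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  config <- pipeline_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  produced <- character(0) # config echo is provenance, not a product
  st <- config$stages

  run_stage <- function(name, enabled, deps_ok, fun) {
    if (!enabled) return(invisible(NULL))
    if (!deps_ok) {
      stop("stage '", name, "' requires its upstream stages to be enabled",
           call. = FALSE)
    }
    written <- character(0)
    tryCatch(
      {
        written <- fun()
        produced <<- c(produced, written)
      },
      error = function(e) {
        for (f in written) {
          if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
        }
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }

  features_env <- new.env(parent = emptyenv())

  run_stage("masks", st$masks, TRUE, function() {
    mk <- config$masks
    arms <- list(control = mk$control_aspect, treated = mk$treated_aspect)
    all_masks <- list()
    truths <- list()
    i <- 0L
    for (arm in names(arms)) {
      for (w in seq_len(mk$n_wells)) {
        i <- i + 1L
        cfg <- shape_config(
          shape = "ellipse", size_px = mk$size_px,
          aspect_ratio = arms[[arm]], pixel_size = mk$pixel_size,
          rotation_deg = 30 * i,
          seed = stage_seed(config, "masks") + i
        )
        g <- gen_cell_masks(cfg, n = mk$n_per_well,
                            well_id = sprintf("%s_w%d", arm, w))
        all_masks <- c(all_masks, g$masks)
        truths[[i]] <- g$truth
      }
    }
    features_env$masks <- all_masks
    written <- character(0)
    written <- write_stage_csv(do.call(rbind, truths), out_dir,
                               "mask_truth.csv", written)
    written
  })

  run_stage("morphometrics", st$morphometrics, st$masks, function() {
    mm <- config$morphometrics
    flt <- filter_cells(features_env$masks, mm$min_intensity,
                        mm$max_pct_touching)
    feats <- compute_features_table(flt$retained)
    n_rej <- table(vapply(flt$rejected, `[[`, character(1L), "well_id"))
    summaries <- do.call(rbind, lapply(split(feats, feats$well_id),
      function(fw) {
        wid <- fw$well_id[1L]
        nf <- if (wid %in% names(n_rej)) n_rej[[wid]] else 0L
        summarize_well(fw, n_filtered = nf)
      }))
    is_treated <- startsWith(summaries$well_id, "treated")
    fc <- fold_change_profile(summaries[is_treated, , drop = FALSE],
                              summaries[!is_treated, , drop = FALSE])
    written <- character(0)
    written <- write_stage_csv(feats, out_dir, "cell_features.csv", written)
    written <- write_stage_csv(summaries, out_dir, "well_summaries.csv",
                               written)
    written <- write_stage_csv(
      data.frame(metric = names(fc), fold_change_minus_1 = as.numeric(fc)),
      out_dir, "fold_change_profile.csv", written)
    written
  })

  run_stage("omics", st$omics, TRUE, function() {
    om <- config$omics
    blocks <- gen_omics_blocks(omics_config(
      n_probes = om$n_probes, n_outputs = om$n_outputs,
      n_latent = om$n_latent, noise_sigma = om$noise_sigma,
      seed = stage_seed(config, "omics")
    ))
    features_env$blocks <- blocks
    written <- character(0)
    written <- write_stage_csv(
      data.frame(condition = rownames(blocks$X), blocks$X,
                 check.names = FALSE),
      out_dir, "omics_X.csv", written)
    written <- write_stage_csv(
      data.frame(condition = rownames(blocks$Y), blocks$Y,
                 check.names = FALSE),
      out_dir, "omics_Y.csv", written)
    written
  })

  run_stage("rppa", st$rppa, st$omics, function() {
    rp <- config$rppa
    raw <- gen_rppa_raw(features_env$blocks$X,
                        n_replicates = rp$n_replicates,
                        control_ligand = rp$control_ligand,
                        seed = stage_seed(config, "rppa"))
    lfc <- log2fc(normalize_to_control(raw, rp$control_ligand))
    ligands <- features_env$blocks$config$ligands
    tops <- lapply(stats::setNames(ligands, ligands), function(lg) {
      select_top_responders(lfc, paste0(lg, "_1h"), rp$fraction)
    })
    venn <- venn_overlaps(tops)
    written <- character(0)
    path_raw <- file.path(out_dir, "rppa_raw.csv")
    write_response_matrix(raw, path_raw)
    written <- c(written, path_raw)
    path_lfc <- file.path(out_dir, "rppa_log2fc.csv")
    write_response_matrix(lfc, path_lfc)
    written <- c(written, path_lfc)
    written <- write_stage_csv(
      data.frame(ligand = rep(names(tops), lengths(tops)),
                 rank = unlist(lapply(tops, seq_along)),
                 probe_id = unlist(tops)),
      out_dir, "rppa_top_responders.csv", written)
    path_venn <- file.path(out_dir, "rppa_venn.json")
    jsonlite::write_json(as.list(venn), path_venn, auto_unbox = TRUE)
    written <- c(written, path_venn)
    written
  })

  run_stage("plsr", st$plsr, st$omics, function() {
    pl <- config$plsr
    Xz <- zscore_block(features_env$blocks$X)
    Yz <- zscore_block(features_env$blocks$Y)
    fit <- fit_plsr(Xz, Yz, n_components = pl$n_components)
    q2 <- loo_q2(Xz, Yz, n_components = pl$n_components)
    cl <- kmeans_loadings(fit, k = pl$k,
                          seed = stage_seed(config, "plsr"))
    al <- alignment_scores(fit, pl$phenotype)
    written <- character(0)
    written <- write_stage_csv(
      data.frame(probe_id = rownames(fit$x_loadings), fit$x_loadings,
                 cluster = cl$assignment,
                 alignment = al, check.names = FALSE),
      out_dir, "plsr_loadings.csv", written)
    written <- write_stage_csv(
      data.frame(n_components = seq_along(fit$r2y_cum),
                 r2x_cum = fit$r2x_cum, r2y_cum = fit$r2y_cum,
                 q2 = q2$q2[seq_along(fit$r2y_cum)]),
      out_dir, "plsr_performance.csv", written)
    written
  })

  run_stage("network", st$network, TRUE, function() {
    nw <- config$network
    spec <- build_nrg1_network(treatment = TRUE)
    sim <- simulate_network(spec, t_end = nw$t_end)
    panel <- run_perturbation_panel(
      spec,
      list(
        PI3Ki = list(node = "PI3K", mode = "ymax_scale",
                     factor = nw$perturb_factor),
        p38i = list(node = "p38", mode = "ymax_scale",
                    factor = nw$perturb_factor)
      ),
      t_end = nw$t_end
    )
    written <- character(0)
    written <- write_stage_csv(tidy_trajectories(sim), out_dir,
                               "network_trajectories.csv", written)
    written <- write_stage_csv(panel, out_dir,
                               "network_perturbations.csv", written)
    path_spec <- file.path(out_dir, "nrg1_network.json")
    write_network_json(spec, path_spec)
    written <- c(written, path_spec)
    written
  })

  manifest <- data.frame(
    file = basename(produced),
    md5 = as.character(tools::md5sum(produced)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
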