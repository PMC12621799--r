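#' Configuration for synthetic protein/phenotype block generation
#'
#' Mirrors the shape of the RPPA screen the pipeline is built for: 172
#' antibody probes measured across four hypertrophic ligands at two
#' timepoints (8 condition rows), coupled to a 15-output phenotype block
#' (11 transcripts + 4 morphology metrics). Both blocks are bilinear in a
#' small number of planted latent factors plus Gaussian noise, which makes
#' latent-structure recovery by PLSR a well-posed test.
#'
#' @param n_probes number of predictor probes (default 172).
#' @param ligands,timepoints condition design; their crossing gives the
#'   condition rows.
#' @param n_outputs number of phenotype outputs (default 15).
#' @param n_latent number of planted latent factors (default 2).
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (>= 0; default 0.05).
#' @param seed RNG seed.
#' @return An `omics_config` list.
#' @export
omics_config <- function(n_probes = 172L,
                         ligands = c("Nrg1", "AngII", "ET1", "IGF1"),
                         timepoints = c("1h", "48h"),
                         n_outputs = 15L, n_latent = 2L,
                         noise_sigma = 0.05, seed = 1L) {
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  n_cond <- length(ligands) * length(timepoints)
  if (n_cond < n_latent + 1L) {
    stop("need at least n_latent + 1 conditions", call. = FALSE)
  }
  structure(
    list(n_probes = as.integer(n_probes), ligands = ligands,
         timepoints = timepoints, n_outputs = as.integer(n_outputs),
         n_latent = as.integer(n_latent), noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "omics_config"
  )
}

#' Generate coupled predictor/response blocks with planted latent structure
#'
#' Draws latent condition scores T (orthogonalized, with decaying factor
#' scales so the components are ordered), probe loadings P and output
#' loadings Q, and returns `X = T P' + noise`, `Y = T Q' + noise` together
#' with the planted T, P, Q for recovery tests. At `noise_sigma = 0`, X has
#' rank `n_latent` exactly and Y is an exact linear image of the scores.
#'
#' @param config an [omics_config()].
#' @return List: `X` (conditions x probes), `Y` (conditions x outputs),
#'   `scores`, `x_loadings`, `y_loadings`, `config`.
#' @export
gen_omics_blocks <- function(config) {
  stopifnot(inherits(config, "omics_config"))
  set.seed(config$seed)
  cond <- as.vector(outer(config$ligands, config$timepoints, paste, sep = "_"))
  n <- length(cond)
  k <- config$n_latent
  Tm <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
  Tm <- Tm %*% diag(2 / seq_len(k), k, k) * sqrt(n)
  P <- matrix(stats::rnorm(config$n_probes * k), config$n_probes, k)
  P <- P / sqrt(rowSums(P^2) + 1e-12)
  Q <- matrix(stats::rnorm(config$n_outputs * k), config$n_outputs, k)
  Q <- Q / sqrt(rowSums(Q^2) + 1e-12)
  X <- Tm %*% t(P) +
    config$noise_sigma * matrix(stats::rnorm(n * config$n_probes), n)
  Y <- Tm %*% t(Q) +
    config$noise_sigma * matrix(stats::rnorm(n * config$n_outputs), n)
  probe_ids <- sprintf("p%03d", seq_len(config$n_probes))
  output_ids <- default_output_names(config$n_outputs)
  dimnames(X) <- list(cond, probe_ids)
  dimnames(Y) <- list(cond, output_ids)
  dimnames(Tm) <- list(cond, paste0("LV", seq_len(k)))
  dimnames(P) <- list(probe_ids, paste0("LV", seq_len(k)))
  dimnames(Q) <- list(output_ids, paste0("LV", seq_len(k)))
  list(X = X, Y = Y, scores = Tm, x_loadings = P, y_loadings = Q,
       config = config)
}

# Phenotype output names: transcript panel then morphology readouts, in the
# spirit of an 11 mRNA + 4 morphology response block.
default_output_names <- function(n_outputs) {
  base <- c("NPPA", "NPPB", "MYH7", "MYH6", "CITED4", "ACTA1", "RCAN1",
            "ATP2A2", "CTGF", "GATA4", "SERPINE1",
            "area", "feret_elongation", "form_factor", "eccentricity")
  if (n_outputs <= length(base)) {
    base[seq_len(n_outputs)]
  } else {
    c(base, sprintf("out%02d", seq_len(n_outputs - length(base))))
  }
}

#' Build a raw RPPA-style matrix embedding known log2 fold-changes
#'
#' Wraps a conditions-by-probes log2 fold-change matrix into the raw,
#' replicated, control-bearing probe-by-condition layout the RPPA
#' preprocessing consumes: each probe gets a lognormal baseline abundance,
#' control (serum-free) columns sit at baseline, and treated columns are
#' `baseline * 2^log2fc` with multiplicative replicate noise. Running
#' [normalize_to_control()], [log2fc()] and [average_replicates()] on the
#' result recovers the embedded matrix up to the replicate noise.
#'
#' @param log2fc_matrix conditions x probes matrix with rownames
#'   `ligand_timepoint`.
#' @param n_replicates replicate columns per condition (default 2).
#' @param replicate_sd standard deviation of the replicate noise on the
#'   log2 scale (default 0.02).
#' @param control_ligand label for the control columns.
#' @param seed RNG seed.
#' @return A raw [response_matrix()] (probes x conditions).
#' @export
gen_rppa_raw <- function(log2fc_matrix, n_replicates = 2L,
                         replicate_sd = 0.02, control_ligand = "serumfree",
                         seed = 1L) {
  set.seed(seed)
  lfc <- t(as.matrix(log2fc_matrix)) # probes x conditions
  n_probes <- nrow(lfc)
  baseline <- stats::rlnorm(n_probes, meanlog = 8, sdlog = 1)
  cond <- parse_conditions(colnames(lfc))
  all_cond <- rbind(
    cond[c("ligand", "timepoint")],
    data.frame(ligand = control_ligand,
               timepoint = unique(cond$timepoint))
  )
  cols <- list()
  for (j in seq_len(nrow(all_cond))) {
    lg <- all_cond$ligand[j]
    tp <- all_cond$timepoint[j]
    shift <- if (lg == control_ligand) {
      numeric(n_probes)
    } else {
      lfc[, paste(lg, tp, sep = "_")]
    }
    for (r in seq_len(n_replicates)) {
      noise <- stats::rnorm(n_probes, 0, replicate_sd)
      cols[[paste(lg, tp, r, sep = "_")]] <- baseline * 2^(shift + noise)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(lfc)
  response_matrix(m, state = "raw")
}
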