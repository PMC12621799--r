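#' The Nrg1 signaling network for cardiomyocyte size and shape
#'
#' Minimal logic-based model of neuregulin-1 signaling: Nrg1 acts through
#' ERBB receptors and activates two cascades, PI3K -> Akt driving both
#' elongation and area, and Ras -> p38 driving area. p38 induces the
#' phosphatase DUSP, which feeds back to inhibit p38 (the AND of Ras
#' activation and DUSP inhibition), producing the transient p38 response.
#' The Area node is driven by an OR over the Akt and p38 branches.
#'
#' Default reaction parameters are w = 1, ec50 = 0.5, n = 1.223; node
#' defaults are yinit = 0, ymax = 1. Receptor-proximal nodes (ERBB, Ras,
#' p38) use tau = 0.1 while PI3K, Akt, DUSP and the phenotype nodes use
#' tau = 1.0, a calibration that reproduces the qualitative timing of the
#' measured responses (fast transient p38, slowly rising Akt). Nrg1 is an
#' input node whose reaction weight is 0.02 at baseline and steps to 0.3
#' under treatment.
#'
#' @param treatment if TRUE (default) the Nrg1 input weight is
#'   `treated_weight` from t = 0; if FALSE it stays at `baseline_weight`.
#' @param baseline_weight,treated_weight Nrg1 input reaction weights
#'   (defaults 0.02 and 0.3).
#' @param tau_overrides optional named numeric vector of per-node time
#'   constants overriding the defaults.
#' @return A [network_spec()].
#' @export
build_nrg1_network <- function(treatment = TRUE, baseline_weight = 0.02,
                               treated_weight = 0.3, tau_overrides = NULL) {
  tau <- c(
    Nrg1 = 0.1, ERBB = 0.1, Ras = 0.1, p38 = 0.1,
    PI3K = 1, Akt = 1, DUSP = 1, Elongation = 1, Area = 1
  )
  if (!is.null(tau_overrides)) {
    unknown <- setdiff(names(tau_overrides), names(tau))
    if (length(unknown)) {
      stop("tau override for unknown node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    tau[names(tau_overrides)] <- tau_overrides
  }
  nodes <- lapply(tau, function(tv) list(tau = tv, yinit = 0, ymax = 1))
  act <- function(id) list(id = id, sign = "activating")
  inh <- function(id) list(id = id, sign = "inhibiting")
  reactions <- list(
    list(sources = list(act("Nrg1")), target = "ERBB"),
    list(sources = list(act("ERBB")), target = "PI3K"),
    list(sources = list(act("PI3K")), target = "Akt"),
    list(sources = list(act("Akt")), target = "Elongation"),
    list(sources = list(act("Akt")), target = "Area"),
    list(sources = list(act("ERBB")), target = "Ras"),
    list(sources = list(act("Ras"), inh("DUSP")), target = "p38",
         gate = "AND"),
    list(sources = list(act("p38")), target = "Area"),
    list(sources = list(act("p38")), target = "DUSP")
  )
  w_in <- if (treatment) treated_weight else baseline_weight
  network_spec(nodes, reactions,
               inputs = list(Nrg1 = matrix(c(0, w_in), 1L, 2L)))
}

#' Steady-state phenotype outputs under a panel of perturbations
#'
#' Runs the base simulation plus one simulation per perturbation and
#' collects the final (steady-state) activity of the requested output
#' nodes. This is the in-silico analogue of co-treating Nrg1-stimulated
#' cells with kinase inhibitors: PI3K or p38 knockout is
#' `ymax_scale = 0` on the corresponding node.
#'
#' @param spec base [network_spec()].
#' @param perturbations named list: condition label -> list with `node`,
#'   `mode`, `factor`.
#' @param outputs node ids to report (default Elongation and Area).
#' @param t_end integration horizon.
#' @return data.frame with columns `condition`, `output`, `steady_state`;
#'   the unperturbed run is condition `"base"`.
#' @export
run_perturbation_panel <- function(spec, perturbations,
                                   outputs = c("Elongation", "Area"),
                                   t_end = 20) {
  stopifnot(inherits(spec, "network_spec"))
  conds <- c(list(base = NULL), perturbations)
  rows <- lapply(names(conds), function(cn) {
    sp <- spec
    pt <- conds[[cn]]
    if (!is.null(pt)) {
      sp <- apply_perturbation(sp, pt$node, pt$mode, pt$factor)
    }
    fin <- simulate_network(sp, t_end = t_end)$final_state
    data.frame(condition = cn, output = outputs,
               steady_state = as.numeric(fin[outputs]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Trajectory timing summaries
#'
#' Peak time, final/peak ratio and time to half of the final value for one
#' node's trajectory — the quantities used to characterize transient
#' (p38-like) versus slowly rising (Akt-like) responses.
#'
#' @param sim a `network_sim`.
#' @param node node id.
#' @return List: `peak_time`, `peak`, `final`, `final_over_peak`,
#'   `t_half_max` (first time the trajectory reaches half its maximum).
#' @export
trajectory_summary <- function(sim, node) {
  stopifnot(inherits(sim, "network_sim"))
  y <- sim$trajectories[, node]
  tm <- sim$times
  ipk <- which.max(y)
  peak <- y[ipk]
  half <- peak / 2
  ihalf <- which(y >= half)[1L]
  list(
    peak_time = tm[ipk],
    peak = peak,
    final = y[length(y)],
    final_over_peak = if (peak > 0) y[length(y)] / peak else NA_real_,
    t_half_max = if (is.na(ihalf)) NA_real_ else tm[ihalf]
  )
}
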