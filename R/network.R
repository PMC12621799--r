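#' Normalized Hill reaction parameters
#'
#' Parameters of one reaction's activation function: weight `w`, Hill
#' coefficient `n` and half-maximal input `ec50`, with the two derived
#' normalization constants
#' `beta = (ec50^n - 1) / (2 ec50^n - 1)` and
#' `k_half = (beta - 1)^(1/n)`,
#' chosen so the activation is pinned to f(0) = 0, f(1) = 1 and
#' f(ec50) = 1/2 on the unit interval. Defaults: w = 1, ec50 = 0.5,
#' n = 1.223. The construction requires `ec50^n < 1/2` (true for the
#' defaults); outside that range the normalization constants are not real.
#'
#' @param w reaction weight in `[0, 1]`.
#' @param n Hill coefficient (> 0).
#' @param ec50 half-maximal input in `(0, 1)`.
#' @return A `hill_params` list with fields `w`, `n`, `ec50`, `beta`,
#'   `k_half`.
#' @export
hill_params <- function(w = 1, n = 1.223, ec50 = 0.5) {
  if (w < 0 || w > 1) stop("`w` must be in [0, 1]", call. = FALSE)
  if (n <= 0) stop("`n` must be > 0", call. = FALSE)
  if (ec50 <= 0 || ec50 >= 1) stop("`ec50` must be in (0, 1)", call. = FALSE)
  e <- ec50^n
  if (e >= 0.5) {
    stop("normalized Hill needs ec50^n < 1/2 (got ", signif(e, 4), ")",
         call. = FALSE)
  }
  beta <- (e - 1) / (2 * e - 1)
  structure(
    list(w = w, n = n, ec50 = ec50, beta = beta,
         k_half = (beta - 1)^(1 / n)),
    class = "hill_params"
  )
}

#' Normalized Hill activation
#'
#' `f(x) = beta * x^n / (k_half^n + x^n)`, monotone non-decreasing on
#' `[0, 1]` with f(0) = 0, f(1) = 1 and f(ec50) = 1/2 by construction.
#'
#' @param x input activity, each element in `[0, 1]`.
#' @param p a [hill_params()] object.
#' @return Activation values in `[0, 1]`, same length as `x`.
#' @export
normalized_hill <- function(x, p = hill_params()) {
  stopifnot(inherits(p, "hill_params"))
  if (any(x < -1e-12 | x > 1 + 1e-12)) {
    stop("normalized_hill input outside [0, 1]", call. = FALSE)
  }
  x <- pmin(pmax(x, 0), 1)
  xn <- x^p$n
  p$beta * xn / ((p$beta - 1) + xn)
}

#' Continuous logic gate combination
#'
#' Combines reaction activations with continuous Boolean logic:
#' `AND` is the product; `OR` is the complement-product (noisy-OR)
#' `1 - prod(1 - a_i)`, associative and with 0 as identity. Inhibiting
#' inputs must be transformed to `1 - f` before combination (the network
#' builder does this).
#'
#' @param activations numeric vector of activations in `[0, 1]`.
#' @param gate `"OR"` or `"AND"`.
#' @return Combined activation in `[0, 1]`.
#' @export
gate_combine <- function(activations, gate = c("OR", "AND")) {
  gate <- match.arg(gate)
  if (length(activations) == 0L) {
    stop("cannot combine an empty activation list", call. = FALSE)
  }
  if (any(activations < -1e-9 | activations > 1 + 1e-9)) {
    stop("activations must lie in [0, 1]", call. = FALSE)
  }
  activations <- pmin(pmax(activations, 0), 1)
  switch(gate,
    OR = 1 - prod(1 - activations),
    AND = prod(activations)
  )
}

#' Signaling network specification
#'
#' Declares the nodes, gated reactions and input schedules of a logic-based
#' differential equation model. Each node carries a time constant `tau`,
#' initial activation `yinit` and maximal activation `ymax` (defaults 0.1,
#' 0, 1). Each reaction lists one or more signed sources (`activating` or
#' `inhibiting`; inhibiting sources enter the gate as `1 - f`), a within-
#' reaction gate (`AND` product for interdependent inputs, `OR` noisy-OR),
#' a target node and Hill parameters. Reactions sharing a target are always
#' OR-combined. Nodes with no incoming reactions follow their piecewise-
#' constant input schedule exactly (they are inputs, not states).
#'
#' @param nodes named list: node id -> list with optional `tau`, `yinit`,
#'   `ymax`.
#' @param reactions list of reactions: each a list with `sources` (list of
#'   `list(id, sign)`), `target`, optional `gate`, `w`, `n`, `ec50`.
#' @param inputs named list: node id -> schedule matrix/list of `(t, w)`
#'   breakpoints, piecewise constant from each breakpoint onward.
#' @return A `network_spec` object.
#' @export
network_spec <- function(nodes, reactions, inputs = list()) {
  node_ids <- names(nodes)
  if (is.null(node_ids) || anyDuplicated(node_ids)) {
    stop("`nodes` must be a uniquely named list", call. = FALSE)
  }
  nodes <- lapply(nodes, function(nd) {
    list(
      tau = if (is.null(nd$tau)) 0.1 else nd$tau,
      yinit = if (is.null(nd$yinit)) 0 else nd$yinit,
      ymax = if (is.null(nd$ymax)) 1 else nd$ymax
    )
  })
  names(nodes) <- node_ids
  for (id in node_ids) {
    nd <- nodes[[id]]
    if (nd$tau <= 0) stop("node '", id, "': tau must be > 0", call. = FALSE)
    if (nd$yinit < 0 || nd$yinit > 1 || nd$ymax < 0 || nd$ymax > 1) {
      stop("node '", id, "': yinit and ymax must be in [0, 1]",
           call. = FALSE)
    }
  }
  seen <- character(0)
  reactions <- lapply(reactions, function(rx) {
    if (is.null(rx$sources) || !length(rx$sources)) {
      stop("reaction without sources (use `inputs` for external drives)",
           call. = FALSE)
    }
    gate <- if (is.null(rx$gate)) "AND" else match.arg(rx$gate, c("AND", "OR"))
    hill <- if (!is.null(rx$hill)) {
      stopifnot(inherits(rx$hill, "hill_params"))
      rx$hill
    } else {
      hill_params(
        w = if (is.null(rx$w)) 1 else as.numeric(rx$w),
        n = if (is.null(rx$n)) 1.223 else as.numeric(rx$n),
        ec50 = if (is.null(rx$ec50)) 0.5 else as.numeric(rx$ec50)
      )
    }
    rx <- list(sources = rx$sources, target = rx$target, gate = gate,
               hill = hill)
    for (s in rx$sources) {
      if (!s$id %in% node_ids) {
        stop("reaction source '", s$id, "' is not a declared node",
             call. = FALSE)
      }
      if (!s$sign %in% c("activating", "inhibiting")) {
        stop("source sign must be 'activating' or 'inhibiting'",
             call. = FALSE)
      }
    }
    if (!rx$target %in% node_ids) {
      stop("reaction target '", rx$target, "' is not a declared node",
           call. = FALSE)
    }
    key <- paste(
      paste(sort(vapply(rx$sources, `[[`, character(1L), "id")),
            collapse = "+"),
      rx$target, sep = "->"
    )
    if (key %in% seen) {
      stop("duplicate reaction ", key, call. = FALSE)
    }
    seen <<- c(seen, key)
    rx
  })
  inputs <- lapply(inputs, function(sch) {
    sch <- matrix(unlist(sch), ncol = 2L, byrow = !is.matrix(sch))
    colnames(sch) <- c("t", "w")
    sch[order(sch[, "t"]), , drop = FALSE]
  })
  if (length(inputs) && !all(names(inputs) %in% node_ids)) {
    stop("input schedule references undeclared node(s)", call. = FALSE)
  }
  structure(
    list(nodes = nodes, reactions = reactions, inputs = inputs),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d nodes, %d reactions, %d input schedule(s)\n",
              length(x$nodes), length(x$reactions), length(x$inputs)))
  invisible(x)
}

# Piecewise-constant schedule lookup (value of the latest breakpoint <= t;
# before the first breakpoint, the first value).
schedule_value <- function(sch, t) {
  i <- findInterval(t, sch[, "t"])
  sch[max(i, 1L), "w"]
}

#' Build the logic-based ODE system for a network
#'
#' For every state node i the dynamics are
#' `dy_i/dt = (ymax_i * F_i(upstream) - y_i) / tau_i`,
#' where `F_i` is the noisy-OR combination over incoming reactions of
#' `w_r * gate(hill terms of the sources)`, inhibiting sources entering as
#' `1 - f`. Input nodes (no incoming reactions, with a schedule) are
#' evaluated algebraically from their schedule; nodes with neither
#' reactions nor schedule decay to 0.
#'
#' @param spec a [network_spec()].
#' @return List: `rhs` (deSolve-style `function(t, y, parms)`),
#'   `state_ids`, `input_ids`, `activity` (function of `(t, y)` giving all
#'   node activities), `spec`.
#' @export
build_odes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  node_ids <- names(spec$nodes)
  has_incoming <- vapply(node_ids, function(id) {
    any(vapply(spec$reactions, function(rx) rx$target == id, logical(1L)))
  }, logical(1L))
  input_ids <- intersect(names(spec$inputs), node_ids[!has_incoming])
  state_ids <- setdiff(node_ids, input_ids)
  tau <- vapply(spec$nodes[state_ids], `[[`, numeric(1L), "tau")
  ymax <- vapply(spec$nodes[state_ids], `[[`, numeric(1L), "ymax")

  rx_by_target <- split(
    spec$reactions,
    factor(vapply(spec$reactions, `[[`, character(1L), "target"),
           levels = state_ids)
  )

  activity <- function(t, y) {
    act <- stats::setNames(numeric(length(node_ids)), node_ids)
    act[state_ids] <- y
    for (id in input_ids) {
      act[id] <- schedule_value(spec$inputs[[id]], t)
    }
    act
  }

  drive <- function(act) {
    vapply(state_ids, function(id) {
      rxs <- rx_by_target[[id]]
      if (!length(rxs)) return(0)
      terms <- vapply(rxs, function(rx) {
        src <- vapply(rx$sources, function(s) {
          f <- normalized_hill(min(max(act[[s$id]], 0), 1), rx$hill)
          if (s$sign == "inhibiting") 1 - f else f
        }, numeric(1L))
        rx$hill$w * gate_combine(src, rx$gate)
      }, numeric(1L))
      gate_combine(terms, "OR")
    }, numeric(1L))
  }

  rhs <- function(t, y, parms) {
    act <- activity(t, y)
    list((ymax * drive(act) - y) / tau)
  }

  list(rhs = rhs, state_ids = state_ids, input_ids = input_ids,
       activity = activity, drive = drive, spec = spec)
}

#' Simulate a network
#'
#' Integrates the logic-based ODE system with an adaptive stiff-capable
#' solver (deSolve's lsoda), restarting at input-schedule breakpoints so
#' step inputs are handled exactly. Node activities stay within
#' `[0, ymax]` by construction of the dynamics; no clipping is applied.
#'
#' @param spec a [network_spec()].
#' @param t_end end time (dimensionless; default 20).
#' @param n_out number of uniformly spaced output times (default 200).
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-10).
#' @return A `network_sim`: `times`, `trajectories` (times x nodes matrix,
#'   input nodes included), `final_state` (named vector over all nodes),
#'   `solver` settings.
#' @export
simulate_network <- function(spec, t_end = 20, n_out = 200L,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0)
  sys <- build_odes(spec)
  times <- seq(0, t_end, length.out = n_out)
  breaks <- sort(unique(unlist(lapply(spec$inputs, function(s) s[, "t"]))))
  breaks <- breaks[breaks > 0 & breaks < t_end]
  y0 <- vapply(spec$nodes[sys$state_ids], `[[`, numeric(1L), "yinit")
  seg_bounds <- unique(c(0, breaks, t_end))
  out_rows <- NULL
  y <- y0
  for (k in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[k]
    t1 <- seg_bounds[k + 1L]
    seg_times <- unique(c(t0, times[times > t0 & times <= t1], t1))
    sol <- deSolve::lsoda(y, seg_times, sys$rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("integration failed in [", t0, ", ", t1, "]: lsoda istate ",
           attr(sol, "istate")[1L], call. = FALSE)
    }
    sol_m <- as.matrix(sol)
    keep <- sol_m[, "time"] %in% times & sol_m[, "time"] > t0 | k == 1L &
      sol_m[, "time"] == 0
    out_rows <- rbind(out_rows, sol_m[keep, , drop = FALSE])
    y <- sol_m[nrow(sol_m), -1L]
  }
  state_traj <- out_rows[, sys$state_ids, drop = FALSE]
  input_traj <- vapply(sys$input_ids, function(id) {
    vapply(out_rows[, "time"], function(t) {
      schedule_value(spec$inputs[[id]], t)
    }, numeric(1L))
  }, numeric(nrow(out_rows)))
  traj <- cbind(state_traj,
                matrix(input_traj, nrow = nrow(out_rows),
                       dimnames = list(NULL, sys$input_ids)))
  traj <- traj[, names(spec$nodes), drop = FALSE]
  structure(
    list(
      times = out_rows[, "time"],
      trajectories = traj,
      final_state = traj[nrow(traj), ],
      solver = list(method = "lsoda", rtol = rtol, atol = atol,
                    t_end = t_end, n_out = n_out)
    ),
    class = "network_sim"
  )
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("<network_sim> %d nodes over t in [0, %g] (%d points)\n",
              ncol(x$trajectories), max(x$times), length(x$times)))
  invisible(x)
}

#' Tidy long-format trajectories
#'
#' @param sim a `network_sim`.
#' @return data.frame with columns `time`, `node`, `activity`.
#' @export
tidy_trajectories <- function(sim) {
  stopifnot(inherits(sim, "network_sim"))
  nodes <- colnames(sim$trajectories)
  data.frame(
    time = rep(sim$times, times = length(nodes)),
    node = rep(nodes, each = length(sim$times)),
    activity = as.vector(sim$trajectories),
    stringsAsFactors = FALSE
  )
}

#' Apply an in-silico perturbation to a network
#'
#' Returns a modified copy of the spec; the original is untouched.
#' `ymax_scale` multiplies the node's maximal activation (factor 0 is a
#' full knockout, the model of a saturating kinase inhibitor);
#' `weight_scale` multiplies the weights of all reactions into the node.
#'
#' @param spec a [network_spec()].
#' @param node node id to perturb.
#' @param mode `"ymax_scale"` or `"weight_scale"`.
#' @param factor multiplier in `[0, 1]`.
#' @return A new `network_spec`.
#' @export
apply_perturbation <- function(spec, node,
                               mode = c("ymax_scale", "weight_scale"),
                               factor = 0) {
  stopifnot(inherits(spec, "network_spec"))
  mode <- match.arg(mode)
  if (!node %in% names(spec$nodes)) {
    stop("unknown node '", node, "'", call. = FALSE)
  }
  if (factor < 0 || factor > 1) stop("`factor` must be in [0, 1]",
                                     call. = FALSE)
  if (mode == "ymax_scale") {
    spec$nodes[[node]]$ymax <- spec$nodes[[node]]$ymax * factor
  } else {
    spec$reactions <- lapply(spec$reactions, function(rx) {
      if (rx$target == node) rx$hill$w <- rx$hill$w * factor
      rx
    })
  }
  spec
}
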