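#' Write a network spec to JSON
#'
#' Serializes the node table, reactions (sources with signs, gate, Hill
#' parameters) and input schedules; [read_network_json()] restores an
#' identical spec.
#'
#' @param spec a [network_spec()].
#' @param path output path.
#' @export
write_network_json <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  obj <- list(
    nodes = lapply(names(spec$nodes), function(id) {
      nd <- spec$nodes[[id]]
      list(id = id, tau = nd$tau, ymax = nd$ymax, yinit = nd$yinit)
    }),
    reactions = lapply(spec$reactions, function(rx) {
      list(
        sources = lapply(rx$sources, function(s) {
          list(id = s$id, sign = s$sign)
        }),
        target = rx$target, gate = rx$gate,
        w = rx$hill$w, n = rx$hill$n, ec50 = rx$hill$ec50
      )
    }),
    inputs = lapply(names(spec$inputs), function(id) {
      sch <- spec$inputs[[id]]
      list(node = id,
           schedule = lapply(seq_len(nrow(sch)),
                             function(i) as.numeric(sch[i, ])))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network spec from JSON
#'
#' @param path path to a JSON file written by [write_network_json()] (or
#'   hand-authored in the same schema).
#' @return A [network_spec()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- stats::setNames(
    lapply(obj$nodes, function(nd) {
      list(tau = nd$tau, yinit = nd$yinit, ymax = nd$ymax)
    }),
    vapply(obj$nodes, `[[`, character(1L), "id")
  )
  reactions <- lapply(obj$reactions, function(rx) {
    list(
      sources = lapply(rx$sources, function(s) {
        list(id = s$id, sign = s$sign)
      }),
      target = rx$target, gate = rx$gate,
      w = rx$w, n = rx$n, ec50 = rx$ec50
    )
  })
  inputs <- stats::setNames(
    lapply(obj$inputs, function(inp) {
      matrix(unlist(inp$schedule), ncol = 2L, byrow = TRUE)
    }),
    vapply(obj$inputs, `[[`, character(1L), "node")
  )
  network_spec(nodes, reactions, inputs)
}

#' Parse a plain-text reaction grammar into a network spec
#'
#' One reaction per line in the form `sources => target`: sources are `&`-
#' separated node ids, `!` marks an inhibiting source (so
#' `"!DUSP & Ras => p38"` is the AND of Ras activation and DUSP
#' inhibition). A line with an empty left side (`"=> Nrg1"`) declares an
#' input node; its weight comes from `input_weights`. All nodes mentioned
#' are declared with default parameters unless overridden via
#' `node_params`. Reactions use default Hill parameters.
#'
#' @param lines character vector of reaction lines; blank lines and lines
#'   starting with `#` are ignored.
#' @param input_weights named numeric vector of input-node weights
#'   (default 1 per input).
#' @param node_params named list of per-node parameter overrides
#'   (`tau`, `yinit`, `ymax`).
#' @return A [network_spec()].
#' @export
parse_reaction_lines <- function(lines, input_weights = NULL,
                                 node_params = NULL) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  reactions <- list()
  input_nodes <- character(0)
  all_ids <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "=>", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("malformed reaction line: '", ln, "'", call. = FALSE)
    }
    target <- trimws(parts[2L])
    if (!nzchar(target)) {
      stop("missing target in line: '", ln, "'", call. = FALSE)
    }
    lhs <- trimws(parts[1L])
    all_ids <- c(all_ids, target)
    if (!nzchar(lhs)) {
      input_nodes <- c(input_nodes, target)
      next
    }
    toks <- trimws(strsplit(lhs, "&", fixed = TRUE)[[1L]])
    sources <- lapply(toks, function(tok) {
      if (startsWith(tok, "!")) {
        list(id = trimws(substring(tok, 2L)), sign = "inhibiting")
      } else {
        list(id = tok, sign = "activating")
      }
    })
    all_ids <- c(all_ids, vapply(sources, `[[`, character(1L), "id"))
    reactions[[length(reactions) + 1L]] <-
      list(sources = sources, target = target, gate = "AND")
  }
  all_ids <- unique(all_ids)
  nodes <- stats::setNames(
    lapply(all_ids, function(id) {
      ov <- node_params[[id]]
      if (is.null(ov)) list() else ov
    }),
    all_ids
  )
  inputs <- list()
  for (id in unique(input_nodes)) {
    w <- if (!is.null(input_weights) && id %in% names(input_weights)) {
      input_weights[[id]]
    } else {
      1
    }
    inputs[[id]] <- matrix(c(0, w), 1L, 2L)
  }
  network_spec(nodes, reactions, inputs)
}
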