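#' Probe-by-condition response matrix
#'
#' Container for RPPA-style measurements: rows are antibody probes
#' (total or phospho-protein), columns are conditions labelled
#' `ligand_timepoint_replicate` (e.g. `"Nrg1_1h_1"`) or, after replicate
#' averaging, `ligand_timepoint`. The normalization state is tracked so the
#' preprocessing steps compose in the right order:
#' raw -> control_normalized -> log2fc (-> zscored in the regression block).
#'
#' @param values numeric matrix with probe rownames and condition colnames.
#' @param state normalization state.
#' @return A `response_matrix` object.
#' @export
response_matrix <- function(values,
                            state = c("raw", "control_normalized",
                                      "log2fc", "zscored")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs probe rownames and condition colnames", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("response matrix contains missing values; drop incomplete probes ",
         "at load time (see read_response_matrix)", call. = FALSE)
  }
  structure(
    list(values = values, state = state),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d probes x %d conditions [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Read a response matrix from CSV/TSV
#'
#' First column is the probe id; remaining columns are conditions named
#' `ligand_timepoint_replicate`. Probes with any missing value are dropped
#' with a message stating how many.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param state normalization state of the stored values (default raw).
#' @return A [response_matrix()].
#' @export
read_response_matrix <- function(path, state = "raw") {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message("dropping ", sum(!complete), " probe(s) with missing values")
    m <- m[complete, , drop = FALSE]
  }
  response_matrix(m, state = state)
}

#' Write a response matrix to CSV
#'
#' @param rm a [response_matrix()].
#' @param path output path.
#' @export
write_response_matrix <- function(rm, path) {
  df <- data.frame(probe_id = rownames(rm$values), rm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parse `ligand_timepoint[_replicate]` condition labels
#'
#' @param labels character vector of condition labels.
#' @return data.frame with columns `ligand`, `timepoint`, `replicate`
#'   (NA when absent).
#' @export
parse_conditions <- function(labels) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  bad <- lengths(parts) < 2L | lengths(parts) > 3L
  if (any(bad)) {
    stop("malformed condition label(s): ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    label = labels,
    ligand = vapply(parts, `[[`, character(1L), 1L),
    timepoint = vapply(parts, `[[`, character(1L), 2L),
    replicate = vapply(parts, function(p) {
      if (length(p) == 3L) p[[3L]] else NA_character_
    }, character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Normalize each probe to its control condition, per timepoint
#'
#' Every treated value is divided by that probe's mean control value at the
#' matching timepoint (protein-loading normalization against the serum-free
#' control). Control columns themselves are normalized too and end up
#' centred on 1.
#'
#' @param rm a raw [response_matrix()].
#' @param control_ligand ligand label of the control condition
#'   (default `"serumfree"`).
#' @return A [response_matrix()] in state `control_normalized`.
#' @export
normalize_to_control <- function(rm, control_ligand = "serumfree") {
  stopifnot(inherits(rm, "response_matrix"))
  if (rm$state != "raw") {
    stop("normalize_to_control expects a raw matrix, got state '",
         rm$state, "'", call. = FALSE)
  }
  cond <- parse_conditions(colnames(rm$values))
  if (!any(cond$ligand == control_ligand)) {
    stop("no control columns with ligand '", control_ligand, "'",
         call. = FALSE)
  }
  out <- rm$values
  for (tp in unique(cond$timepoint)) {
    ctrl_cols <- which(cond$ligand == control_ligand & cond$timepoint == tp)
    tp_cols <- which(cond$timepoint == tp)
    if (!length(ctrl_cols)) {
      stop("no control columns for timepoint '", tp, "'", call. = FALSE)
    }
    ctrl_mean <- rowMeans(rm$values[, ctrl_cols, drop = FALSE])
    if (any(ctrl_mean <= 0)) {
      bad <- rownames(rm$values)[ctrl_mean <= 0][1L]
      stop("non-positive control value for probe '", bad,
           "' at timepoint '", tp, "'", call. = FALSE)
    }
    out[, tp_cols] <- rm$values[, tp_cols, drop = FALSE] / ctrl_mean
  }
  response_matrix(out, state = "control_normalized")
}

#' Elementwise log2 of a control-normalized matrix
#'
#' @param rm a [response_matrix()] in state `control_normalized`.
#' @return A [response_matrix()] in state `log2fc`.
#' @export
log2fc <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  if (rm$state != "control_normalized") {
    stop("log2fc expects a control-normalized matrix, got state '",
         rm$state, "'", call. = FALSE)
  }
  if (any(rm$values <= 0)) {
    bad <- rownames(rm$values)[apply(rm$values <= 0, 1L, any)][1L]
    stop("non-positive normalized value for probe '", bad, "'",
         call. = FALSE)
  }
  response_matrix(log2(rm$values), state = "log2fc")
}

#' Average replicate columns per ligand-timepoint condition
#'
#' @param rm a [response_matrix()].
#' @return A [response_matrix()] with one column per `ligand_timepoint`,
#'   same state.
#' @export
average_replicates <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  cond <- parse_conditions(colnames(rm$values))
  key <- paste(cond$ligand, cond$timepoint, sep = "_")
  keys <- unique(key)
  out <- vapply(keys, function(k) {
    rowMeans(rm$values[, key == k, drop = FALSE])
  }, numeric(nrow(rm$values)))
  out <- matrix(out, nrow = nrow(rm$values),
                dimnames = list(rownames(rm$values), keys))
  response_matrix(out, state = rm$state)
}

#' Select the top-responding probes in a condition
#'
#' Ranks probes by the magnitude of their log2 fold-change in the stated
#' `ligand_timepoint` condition (replicates averaged first) and returns the
#' top `ceiling(fraction * n_probes)`. Absolute ranking captures both up-
#' and down-regulation and is the default; `ranking = "signed"` ranks by
#' signed change instead. Boundary ties break lexicographically by probe id
#' so the selection is deterministic.
#'
#' @param rm a [response_matrix()] in state `log2fc`.
#' @param condition `ligand_timepoint` label, e.g. `"Nrg1_1h"`.
#' @param fraction fraction of probes to keep, in `(0, 1]` (default 0.20).
#' @param ranking `"absolute"` (default) or `"signed"`.
#' @return Character vector of probe ids, ranked from strongest response.
#' @export
select_top_responders <- function(rm, condition, fraction = 0.20,
                                  ranking = c("absolute", "signed")) {
  stopifnot(inherits(rm, "response_matrix"))
  ranking <- match.arg(ranking)
  if (rm$state != "log2fc") {
    stop("select_top_responders expects log2 fold-changes, got state '",
         rm$state, "'", call. = FALSE)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  avg <- average_replicates(rm)
  if (!condition %in% colnames(avg$values)) {
    stop("unknown condition '", condition, "'; available: ",
         paste(colnames(avg$values), collapse = ", "), call. = FALSE)
  }
  x <- avg$values[, condition]
  score <- if (ranking == "absolute") abs(x) else x
  ord <- order(-score, names(x), method = "radix")
  n_top <- ceiling(fraction * length(x))
  names(x)[ord][seq_len(n_top)]
}

#' Venn region counts for 2-4 probe sets
#'
#' Partitions the union of the given sets into the 2^k - 1 exclusive Venn
#' regions and counts each; counts therefore sum to the union size.
#'
#' @param sets named list of 2-4 character vectors (e.g. one top-responder
#'   set per ligand).
#' @return Named integer vector; names like `"Nrg1"`, `"Nrg1&AngII"` list
#'   exactly the sets a region's members belong to.
#' @export
venn_overlaps <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("venn_overlaps needs 2-4 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = k,
                       dimnames = list(universe, names(sets)))
  region_of <- apply(membership, 1L, function(b) {
    paste(names(sets)[b], collapse = "&")
  })
  all_regions <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(sets), m, paste, collapse = "&")
  }))
  counts <- table(factor(region_of, levels = all_regions))
  stats::setNames(as.integer(counts), all_regions)
}
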