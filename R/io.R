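#' Write a sweep set to the canonical delimited container
#'
#' The canonical container is a pair of plain-text files: `<stem>.tsv`
#' holding the samples in long format (columns `sweep`, `t`, and one
#' column per channel) and a `<stem>.json` sidecar holding the protocol,
#' conditions, cell id, metadata and the liquid-junction-potential state.
#'
#' @param ss A [sweep_set()].
#' @param path Path to the `.tsv` file (sidecar written alongside).
#' @return `path`, invisibly.
#' @seealso [read_sweepset()]
#' @export
write_sweepset <- function(ss, path) {
  stopifnot(inherits(ss, "sweep_set"))
  frames <- lapply(seq_along(ss$sweeps), function(i) {
    sw <- ss$sweeps[[i]]
    d <- data.frame(sweep = i, t = sweep_times(sw))
    for (ch in c("voltage", "current", "stimulus"))
      if (!is.null(sw[[ch]])) d[[ch]] <- sw[[ch]]
    d
  })
  dat <- do.call(rbind, frames)
  utils::write.table(dat, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- list(
    cell_id = ss$cell_id,
    protocol = unclass(ss$protocol),
    dt = ss$sweeps[[1]]$dt,
    t0 = vapply(ss$sweeps, `[[`, numeric(1), "t0"),
    condition = vapply(ss$sweeps, `[[`, character(1), "condition"),
    ljp_corrected = vapply(ss$sweeps, `[[`, logical(1), "ljp_corrected"),
    metadata = ss$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")

#' Read a sweep set from the canonical delimited container
#'
#' Voltages are stored in the amplifier frame; on read the liquid
#' junction potential (`ljp`, default 15 mV as used for K-gluconate
#' internal solutions) is subtracted from the voltage channel exactly
#' once, guarded by the per-sweep `ljp_corrected` flag in the sidecar.
#'
#' @param path Path to the `.tsv` file written by [write_sweepset()].
#' @param ljp Liquid junction potential (mV) to subtract on load.
#' @return A [sweep_set()] with `ljp_corrected = TRUE` voltage sweeps.
#' @export
read_sweepset <- function(path, ljp = 15) {
  if (!file.exists(path)) stop("file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing protocol sidecar: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  dat <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("sweep", "t")
  if (!all(need %in% names(dat))) stop("malformed trace table")
  prot <- side$protocol
  if (is.null(prot$kind)) stop("missing protocol block")
  class(prot) <- "protocol"
  idx <- sort(unique(dat$sweep))
  sweeps <- lapply(seq_along(idx), function(k) {
    rows <- dat[dat$sweep == idx[k], , drop = FALSE]
    corrected <- isTRUE(side$ljp_corrected[k])
    v <- if ("voltage" %in% names(rows)) rows$voltage else NULL
    if (!is.null(v) && !corrected) v <- v - ljp
    sweep_trace(t0 = side$t0[k], dt = side$dt, voltage = v,
                current = if ("current" %in% names(rows)) rows$current,
                stimulus = if ("stimulus" %in% names(rows)) rows$stimulus,
                condition = side$condition[k],
                ljp_corrected = !is.null(v) || corrected)
  })
  md <- side$metadata
  if (is.null(md)) md <- list()
  sweep_set(sweeps, prot, cell_id = side$cell_id, metadata = md)
}

#' Read an SWC morphology reconstruction
#'
#' Standard 7-column SWC dialect: `id type x y z radius parent`,
#' whitespace-separated, `#` comments. Coordinates and radii in
#' micrometres. The file must define exactly one root (`parent = -1`)
#' and every parent before its children, which also guarantees
#' acyclicity.
#'
#' @param path Path to an `.swc` file.
#' @return An object of class `"morphology"`: a list with `nodes`
#'   (data frame `id, type, x, y, z, radius, parent`) and `soma_id`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SWC file")
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7L)) stop("SWC rows must have 7 columns")
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (anyNA(m)) stop("non-numeric field in SWC file")
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  morphology(nodes)
}

#' Construct and validate a morphology
#'
#' @param nodes Data frame with columns `id, type, x, y, z, radius,
#'   parent` (SWC conventions; `parent = -1` marks the root).
#' @return An object of class `"morphology"`.
#' @export
morphology <- function(nodes) {
  stopifnot(all(c("id", "type", "x", "y", "z", "radius", "parent")
                %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  roots <- nodes$id[nodes$parent == -1]
  if (length(roots) != 1L) stop("morphology must have exactly one root")
  pos <- match(nodes$parent, nodes$id)
  bad <- nodes$parent != -1 & is.na(pos)
  if (any(bad)) stop("orphan parent id: ", nodes$parent[bad][1])
  if (any(pos >= seq_len(nrow(nodes)), na.rm = TRUE))
    stop("parent defined after child (or cycle)")
  structure(list(nodes = nodes, soma_id = roots), class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %d nodes, %d endpoints, soma id %g\n",
              nrow(x$nodes), length(endpoint_ids(x)), x$soma_id))
  invisible(x)
}

endpoint_ids <- function(morph) {
  n <- morph$nodes
  setdiff(n$id[!(n$id %in% n$parent)], morph$soma_id)
}

#' Write a morphology as SWC
#'
#' @param morph A [morphology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  n <- morph$nodes
  lines <- sprintf("%g %g %.9g %.9g %.9g %.9g %g",
                   n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# SWC written by l7ephys", lines), path)
  invisible(path)
}

#' Segmented-object field: bouton polygons and puncta centres
#'
#' @param boutons List of two-column matrices, one simple polygon per
#'   bouton (vertices in order, micrometres, not closed).
#' @param puncta Two-column matrix of punctum centres.
#' @param cell_perimeter Optional two-column matrix, the traced cell
#'   perimeter polygon.
#' @return An object of class `"object_field"`.
#' @export
object_field <- function(boutons, puncta, cell_perimeter = NULL) {
  boutons <- lapply(boutons, as_poly)
  puncta <- matrix(as.numeric(puncta), ncol = 2)
  if (!all(is.finite(puncta))) stop("non-finite puncta coordinates")
  for (b in boutons)
    if (!polygon_is_simple(b)) stop("bouton polygon self-intersects")
  if (!is.null(cell_perimeter)) {
    cell_perimeter <- as_poly(cell_perimeter)
    if (!polygon_is_simple(cell_perimeter))
      stop("perimeter polygon self-intersects")
  }
  structure(list(boutons = boutons, puncta = puncta,
                 cell_perimeter = cell_perimeter),
            class = "object_field")
}

as_poly <- function(p) {
  p <- matrix(as.numeric(as.matrix(p)), ncol = 2)
  if (nrow(p) < 3) stop("polygon needs >= 3 vertices")
  if (!all(is.finite(p))) stop("non-finite polygon coordinates")
  # drop a repeated closing vertex
  if (all(abs(p[1, ] - p[nrow(p), ]) < 1e-12)) p <- p[-nrow(p), , drop = FALSE]
  p
}

#' @export
print.object_field <- function(x, ...) {
  cat(sprintf("<object_field> %d boutons, %d puncta%s\n",
              length(x$boutons), nrow(x$puncta),
              if (is.null(x$cell_perimeter)) "" else ", with perimeter"))
  invisible(x)
}

#' Write / read a per-cell feature table
#'
#' Tab-delimited text, one row per cell, first column `cell_id`,
#' remaining columns the feature values at full precision.
#'
#' @param features Data frame with a `cell_id` column plus numeric
#'   feature columns.
#' @param path Output `.tsv` path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  if (!"cell_id" %in% names(features))
    features <- cbind(cell_id = rownames(features), features)
  fmt <- features
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
  utils::write.table(fmt, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
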