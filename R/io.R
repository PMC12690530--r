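#' Write / read a cytokine panel as wide CSV
#'
#' Wide format: `animal_id, group, replicate`, then one column per
#' cytokine; out-of-range entries are serialized as the literal token
#' `OOR` and read back as flagged (`NA`) values.
#'
#' @param panel Panel tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a panel tibble (reader).
#' @export
write_panel_csv <- function(panel, path) {
  check_panel(panel)
  out <- as.data.frame(panel)
  for (cy in cytokine_cols(panel)) {
    v <- format(out[[cy]], trim = TRUE, digits = 15)
    v[is.na(out[[cy]])] <- "OOR"
    out[[cy]] <- v
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  panel <- as_tibble(raw)
  panel$replicate <- as.integer(panel$replicate)
  for (cy in setdiff(names(panel), panel_id_cols)) {
    v <- panel[[cy]]
    v[v == "OOR"] <- NA
    panel[[cy]] <- as.numeric(v)
  }
  check_panel(panel)
  class(panel) <- c("cytokine_panel", class(panel))
  panel
}

#' Write / read a loading trace as 3-column CSV
#'
#' Columns `time_s, displacement_um, force_N`.
#'
#' @param trace Trace tibble.
#' @param path CSV path.
#' @param frequency,amplitude Nominal protocol values attached as
#'   attributes on read (optional).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("time_s", "displacement_um", "force_N") %in% names(trace)))
  write.csv(as.data.frame(trace)[c("time_s", "displacement_um", "force_N")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, frequency = NULL, amplitude = NULL) {
  tr <- as_tibble(read.csv(path))
  stopifnot(all(c("time_s", "displacement_um", "force_N") %in% names(tr)))
  attr(tr, "frequency") <- frequency
  attr(tr, "amplitude") <- amplitude
  class(tr) <- c("loading_trace", class(tr))
  tr
}

#' Write / read a GTT series as 2-column CSV
#'
#' Columns `time_h, glucose_mg_dl`.
#' @param series GTT tibble.
#' @param path CSV path.
#' @export
write_gtt_csv <- function(series, path) {
  stopifnot(all(c("time_h", "glucose_mg_dl") %in% names(series)))
  write.csv(as.data.frame(series)[c("time_h", "glucose_mg_dl")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_gtt_csv
#' @export
read_gtt_csv <- function(path) {
  s <- as_tibble(read.csv(path))
  stopifnot(all(c("time_h", "glucose_mg_dl") %in% names(s)))
  s
}

#' Write / read a disc volume as a multi-page TIFF stack with JSON sidecar
#'
#' One 32-bit float TIFF page per transverse slice, plus `<path>.json`
#' recording the voxel size in micrometres. Intensities are stored
#' unscaled.
#'
#' @param vol A `disc_volume`.
#' @param path TIFF path (the sidecar gets `.json` appended).
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "disc_volume"))
  # TIFF float samples are stored in [0, 1]; rescale and record the factor
  # (and any negative offset from noise) in the sidecar.
  offset <- min(vol$data, 0)
  scale <- max(vol$data - offset, 1e-12)
  data <- (vol$data - offset) / scale
  pages <- lapply(seq_len(dim(data)[1]), function(k) data[k, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(voxel_size_um = vol$voxel_size, intensity_scale = scale,
         intensity_offset = offset),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param voxel_size Voxel size override when no sidecar is present.
#' @export
read_volume_tiff <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  vol <- array(0, c(length(pages), d2[1], d2[2]))
  for (k in seq_along(pages)) vol[k, , ] <- pages[[k]]
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(voxel_size)) {
    if (is.null(meta$voxel_size_um)) {
      stop_ivd("No voxel size: provide `voxel_size` or a JSON sidecar.", "bad_volume")
    }
    voxel_size <- meta$voxel_size_um
  }
  if (!is.null(meta$intensity_scale)) {
    vol <- vol * meta$intensity_scale + (meta$intensity_offset %||% 0)
  }
  disc_volume(vol, voxel_size)
}

#' Write a mask set as multi-page TIFF stacks
#'
#' Writes `<stem>_disc.tif` and `<stem>_np.tif` (0/1 float pages).
#' @param masks A `mask_set`.
#' @param stem Output path stem.
#' @export
write_masks_tiff <- function(masks, stem) {
  stopifnot(inherits(masks, "mask_set"))
  for (nm in c("disc", "np")) {
    m <- masks[[nm]] * 1
    pages <- lapply(seq_len(dim(m)[1]), function(k) m[k, , ])
    tiff::writeTIFF(pages, paste0(stem, "_", nm, ".tif"),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(stem)
}

#' Write / read contour sets as JSON
#'
#' JSON object: slice index (as key) -> list of `[row, col]` vertices.
#' @param contours A `contour_set`.
#' @param path JSON path.
#' @export
write_contours_json <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  obj <- stats::setNames(
    lapply(contours$polygons, function(p) unname(apply(p, 1, c, simplify = FALSE))),
    contours$slices
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::read_json(path)
  contours <- lapply(obj, function(pl) {
    do.call(rbind, lapply(pl, function(v) as.numeric(unlist(v))))
  })
  contour_set(contours)
}

#' Export a cytokine network as GraphML and edge-list CSV
#'
#' @param net A `cytokine_network`.
#' @param graphml_path Optional GraphML output path.
#' @param edges_path Optional edge-list CSV path (`source, target, r`).
#' @return The edge tibble, invisibly.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  stopifnot(inherits(net, "cytokine_network"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  ed <- network_edges(net)
  if (!is.null(edges_path)) {
    write.csv(as.data.frame(ed), edges_path, row.names = FALSE)
  }
  invisible(ed)
}

#' Read a network from an edge-list CSV
#'
#' @param path CSV with columns `source, target, r`.
#' @param nodes Optional node superset (to retain isolated nodes).
#' @param tau Threshold to record.
#' @export
read_network_edges <- function(path, nodes = NULL, tau = 0.7) {
  network_from_edges(read.csv(path), nodes = nodes, tau = tau)
}
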