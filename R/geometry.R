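#' Cell geometry objects
#'
#' A geometry set maps each `cell_id` to a cell boundary and a nucleus
#' boundary. Boundaries are either discs (`disc_boundary()`, exact distances;
#' what the simulator emits) or simple closed polygons (`polygon_boundary()`;
#' what segmentation masks export). Both share a coordinate frame, in
#' micrometres, with the transcript table.
#'
#' @param center numeric length-2 disc center.
#' @param r disc radius (> 0).
#' @return a boundary object.
#' @export
disc_boundary <- function(center, r) {
  stopifnot(length(center) == 2, r > 0)
  structure(list(type = "disc", center = as.numeric(center), r = r),
            class = "dcoloc_boundary")
}

#' @rdname disc_boundary
#' @param xy n x 2 matrix of polygon vertices (closed implicitly; the last
#'   vertex need not repeat the first).
#' @export
polygon_boundary <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  structure(list(type = "poly", xy = xy), class = "dcoloc_boundary")
}

#' Assemble a geometry set
#' @param cell_ids character vector.
#' @param cell,nucleus lists of boundary objects, parallel to `cell_ids`.
#' @return named list of `list(cell=, nucleus=)`, class `cell_geometry_set`.
#' @export
cell_geometry_set <- function(cell_ids, cell, nucleus) {
  stopifnot(length(cell_ids) == length(cell), length(cell) == length(nucleus))
  out <- mapply(function(cb, nb) list(cell = cb, nucleus = nb),
                cell, nucleus, SIMPLIFY = FALSE)
  names(out) <- as.character(cell_ids)
  class(out) <- "cell_geometry_set"
  out
}

# inside test for a boundary, vectorized over points
.geom_inside <- function(b, x, y) {
  if (b$type == "disc") {
    (x - b$center[1])^2 + (y - b$center[2])^2 <= b$r^2
  } else {
    pracma::inpolygon(x, y, b$xy[, 1], b$xy[, 2], boundary = TRUE)
  }
}

# Euclidean distance from points to the boundary curve (not the region)
.geom_boundary_dist <- function(b, x, y) {
  if (b$type == "disc") {
    abs(sqrt((x - b$center[1])^2 + (y - b$center[2])^2) - b$r)
  } else {
    .dist_to_polyline(x, y, b$xy)
  }
}

# min distance from each point to a closed polyline (polygon edges)
.dist_to_polyline <- function(px, py, xy) {
  n <- nrow(xy)
  ax <- xy[, 1]; ay <- xy[, 2]
  bx <- xy[c(2:n, 1), 1]; by <- xy[c(2:n, 1), 2]
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- 1e-300
  best <- rep(Inf, length(px))
  for (s in seq_len(n)) {
    t <- ((px - ax[s]) * ex[s] + (py - ay[s]) * ey[s]) / len2[s]
    t <- pmin(1, pmax(0, t))
    dx <- px - (ax[s] + t * ex[s])
    dy <- py - (ay[s] + t * ey[s])
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

#' Load cell/nucleus boundaries from GeoJSON
#'
#' Expects a FeatureCollection with one Polygon Feature per boundary and
#' properties `cell_id` and `role` (`"cell"` or `"nucleus"`).
#'
#' @param path GeoJSON file.
#' @return `cell_geometry_set`.
#' @export
load_geometry <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  acc <- list()
  for (f in gj$features) {
    cid <- as.character(f$properties$cell_id)
    role <- f$properties$role
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (is.null(acc[[cid]])) acc[[cid]] <- list()
    acc[[cid]][[role]] <- polygon_boundary(xy)
  }
  miss <- names(acc)[!vapply(acc, function(e)
    all(c("cell", "nucleus") %in% names(e)), logical(1))]
  if (length(miss))
    stop("cell(s) missing a cell or nucleus boundary: ",
         paste(miss, collapse = ", "))
  cell_geometry_set(names(acc),
                    lapply(acc, `[[`, "cell"),
                    lapply(acc, `[[`, "nucleus"))
}

#' Write a geometry set as GeoJSON
#' @param geometry `cell_geometry_set`.
#' @param path output file.
#' @param n_vertices number of vertices used to polygonize disc boundaries.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path, n_vertices = 64L) {
  poly_coords <- function(b) {
    if (b$type == "disc") {
      th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
      xy <- cbind(b$center[1] + b$r * cos(th), b$center[2] + b$r * sin(th))
    } else xy <- b$xy
    xy <- rbind(xy, xy[1, ])
    list(lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2])))
  }
  feats <- list()
  for (cid in names(geometry)) {
    for (role in c("cell", "nucleus")) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(cell_id = cid, role = role),
        geometry = list(type = "Polygon",
                        coordinates = poly_coords(geometry[[cid]][[role]])))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assign subcellular region labels to transcripts
#'
#' Labels every transcript with one of four regions forming a partition:
#' \describe{
#'   \item{PN}{peri-nucleus: within `pn_halfwidth` of the nuclear membrane,
#'     on either side of it (takes precedence over Nuc/Cyt).}
#'   \item{Nuc}{inside the nucleus, beyond the PN band.}
#'   \item{CP}{cell periphery: outside nucleus/PN, within `cp_width` of the
#'     cell membrane.}
#'   \item{Cyt}{everything else.}
#' }
#' A single 2D boundary per cell is applied to all z-planes. A transcript
#' falling outside its cell boundary triggers a warning and is labeled by the
#' nearest region (PN if within the PN band, else CP).
#'
#' @param table transcript table.
#' @param geometry `cell_geometry_set` covering every cell in `table`.
#' @param pn_halfwidth micrometres on either side of the nuclear membrane
#'   (default 2.5).
#' @param cp_width micrometres inside the cell membrane (default 4).
#' @return transcript table with a `region` factor column.
#' @export
assign_regions <- function(table, geometry, pn_halfwidth = 2.5, cp_width = 4) {
  stopifnot(pn_halfwidth > 0, cp_width > 0)
  cells <- unique(table$cell)
  miss <- setdiff(cells, names(geometry))
  if (length(miss)) stop("no geometry for cell(s): ", paste(miss, collapse = ", "))
  region <- character(nrow(table))
  in_nucleus <- logical(nrow(table))
  n_outside <- 0L
  for (cid in cells) {
    ii <- which(table$cell == cid)
    g <- geometry[[cid]]
    x <- table$x[ii]; y <- table$y[ii]
    d_nuc <- .geom_boundary_dist(g$nucleus, x, y)
    in_nuc <- .geom_inside(g$nucleus, x, y)
    d_cell <- .geom_boundary_dist(g$cell, x, y)
    in_cell <- .geom_inside(g$cell, x, y)
    lab <- ifelse(d_nuc <= pn_halfwidth, "PN",
           ifelse(in_nuc, "Nuc",
           ifelse(d_cell <= cp_width, "CP", "Cyt")))
    out <- !in_cell & lab %in% c("Cyt", "Nuc")
    if (any(out)) {  # outside the cell: snap to the nearest region
      lab[out] <- ifelse(d_nuc[out] <= pn_halfwidth, "PN", "CP")
      n_outside <- n_outside + sum(out)
    }
    region[ii] <- lab
    in_nucleus[ii] <- in_nuc
  }
  if (n_outside > 0)
    warning(n_outside, " transcript(s) outside their cell boundary; ",
            "labeled by nearest region")
  table$region <- factor(region, levels = .REGIONS)
  table$in_nucleus <- in_nucleus  # used by the intra-nucleus PP mode
  table
}
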