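#' Node specification for an intrinsic connectivity network
#'
#' @param name node label (e.g. "mPFC").
#' @param hemisphere one of "L", "R", "midline".
#' @param peak_mm length-3 peak coordinate in mm (x left-right,
#'   y anterior-posterior, z dorsal-ventral).
#' @param radius_mm node extent; the node is modelled as an isotropic
#'   Gaussian bump with SD = `radius_mm / 2`.
#' @return one-row data frame.
#' @export
node_spec <- function(name, hemisphere, peak_mm, radius_mm = 8) {
  stopifnot(is.character(name), length(peak_mm) == 3, radius_mm > 0)
  hemisphere <- match.arg(hemisphere, c("L", "R", "midline"))
  data.frame(name = name, hemisphere = hemisphere,
             x = peak_mm[1], y = peak_mm[2], z = peak_mm[3],
             radius_mm = radius_mm, stringsAsFactors = FALSE)
}

#' Network specification
#'
#' @param name network label (DMN, SN, FPN, VN, AN, CEN, SMN).
#' @param nodes data frame of node rows as built by [node_spec()].
#' @param timecourse_seed integer seed offset for this network's
#'   simulated time course.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(name, nodes, timecourse_seed = 0L) {
  stopifnot(nrow(nodes) >= 1, !anyDuplicated(nodes$name))
  structure(list(name = name, nodes = nodes,
                 timecourse_seed = as.integer(timecourse_seed)),
            class = "network_spec")
}

nodes_df <- function(...) do.call(rbind, list(...))

#' Canonical network node tables
#'
#' Seven intrinsic connectivity networks. DMN, FPN, SN and VN use published
#' peak coordinates of the group networks; AN, CEN and SMN are synthetic
#' templates built from literature-typical peak locations (no group table is
#' available for them here) and are used only as negative templates.
#'
#' @return named list of `network_spec` objects.
#' @export
default_networks <- function() {
  dmn <- nodes_df(
    node_spec("IPL/SMG_R", "R", c(50, -59, 24)),
    node_spec("mPFC",      "L", c(-4,  49, 21)),
    node_spec("PCC",       "L", c(-1, -53, 21)),
    node_spec("IPL_L",     "L", c(-49, -62, 27)),
    node_spec("IFG_L",     "L", c(-43, 19, -6))
  )
  fpn <- nodes_df(
    node_spec("SPL/IPS_R", "R", c(38, -62, 48)),
    node_spec("MFG_R",     "R", c(44,   7, 42)),
    node_spec("PCUN_R",    "R", c(2,  -65, 36)),
    node_spec("AFC_R",     "R", c(32,  52,  9)),
    node_spec("ITG_R",     "R", c(59, -35, -3)),
    node_spec("ATP_L",     "L", c(-46, -13, -15)),
    node_spec("MFG_L",     "L", c(-28, 10, 51)),
    node_spec("SPL_L",     "L", c(-43, -59, 39))
  )
  sn <- nodes_df(
    node_spec("AI/IFG_R",  "R", c(44, 13, 0)),
    node_spec("AI_L",      "L", c(-43, 10, 0)),
    node_spec("SFG_R",     "R", c(29, 49, 27)),
    node_spec("ACC_R",     "R", c(2, 31, 30)),
    node_spec("MPCC_L",    "L", c(1, -23, 27)),
    node_spec("SFG_L",     "L", c(-7, 19, 57)),
    node_spec("MFG_L",     "L", c(-31, 46, 30))
  )
  vn <- nodes_df(node_spec("VisualCortex", "R", c(2, -71, 3)))
  an <- nodes_df(
    node_spec("STG_R", "R", c(52, -20, 8)),
    node_spec("STG_L", "L", c(-52, -20, 8))
  )
  cen <- nodes_df(
    node_spec("dlPFC_R", "R", c(46, 38, 24)),
    node_spec("dlPFC_L", "L", c(-44, 38, 24))
  )
  smn <- nodes_df(
    node_spec("PreCG_R", "R", c(38, -26, 50)),
    node_spec("PreCG_L", "L", c(-38, -26, 50)),
    node_spec("SMA",     "midline", c(0, -10, 58))
  )
  list(
    DMN = network_spec("DMN", dmn, 1L),
    SN  = network_spec("SN",  sn,  2L),
    FPN = network_spec("FPN", fpn, 3L),
    VN  = network_spec("VN",  vn,  4L),
    AN  = network_spec("AN",  an,  5L),
    CEN = network_spec("CEN", cen, 6L),
    SMN = network_spec("SMN", smn, 7L)
  )
}

#' The four networks planted in the synthetic cohort
#' @return named list of `network_spec` objects (DMN, SN, FPN, VN).
#' @export
planted_networks <- function() default_networks()[c("DMN", "SN", "FPN", "VN")]

#' Gaussian node bump on a grid
#'
#' Isotropic Gaussian with SD = `radius_mm / 2` centred at `peak_mm`,
#' evaluated at voxel centres (peak value 1 at the exact peak position).
#' @param grid a `vox_grid`.
#' @param peak_mm length-3 mm coordinate.
#' @param radius_mm node radius in mm.
#' @return numeric 3-D array.
#' @export
gaussian_bump <- function(grid, peak_mm, radius_mm = 8) {
  sd <- radius_mm / 2
  ax <- grid_axes(grid)
  gx <- exp(-0.5 * ((ax$x - peak_mm[1]) / sd)^2)
  gy <- exp(-0.5 * ((ax$y - peak_mm[2]) / sd)^2)
  gz <- exp(-0.5 * ((ax$z - peak_mm[3]) / sd)^2)
  b <- outer(outer(gx, gy), gz)
  dim(b) <- grid$dim
  b
}

#' Build a network atlas on a grid
#'
#' Each network's spatial map is the sum of isotropic Gaussian bumps
#' (SD = radius/2) centred at its node peaks, max-normalised to 1.
#' The voxel index of each node peak is recorded.
#'
#' @param networks list of `network_spec` objects.
#' @param grid a `vox_grid`.
#' @param radius_mm default node radius used when a node does not carry
#'   its own.
#' @return object of class `icn_atlas`: list with `grid`, `radius_mm` and
#'   `networks` (per network: `spec`, `map`, `nodes` with voxel indices).
#' @export
make_network_atlas <- function(networks, grid, radius_mm = 8) {
  stopifnot(radius_mm > 0)
  nets <- lapply(networks, function(ns) {
    nd <- ns$nodes
    if (is.null(nd) || nrow(nd) == 0) {
      map <- array(0, grid$dim)
      return(list(spec = ns, map = map,
                  nodes = cbind(nd, data.frame(ix = integer(0), iy = integer(0),
                                               iz = integer(0)))))
    }
    map <- array(0, grid$dim)
    idx <- matrix(NA_integer_, nrow(nd), 3)
    for (i in seq_len(nrow(nd))) {
      pk <- c(nd$x[i], nd$y[i], nd$z[i])
      if (!in_grid(grid, pk))
        stop(sprintf("node '%s' of network '%s' lies outside the grid",
                     nd$name[i], ns$name))
      r <- if (!is.null(nd$radius_mm)) nd$radius_mm[i] else radius_mm
      map <- map + gaussian_bump(grid, pk, r)
      idx[i, ] <- mm_to_voxel(grid, pk)
    }
    if (max(map) > 0) map <- map / max(map)
    nd$ix <- idx[, 1]; nd$iy <- idx[, 2]; nd$iz <- idx[, 3]
    list(spec = ns, map = map, nodes = nd)
  })
  names(nets) <- vapply(networks, function(n) n$name, "")
  structure(list(grid = grid, radius_mm = radius_mm, networks = nets),
            class = "icn_atlas")
}

#' @export
print.icn_atlas <- function(x, ...) {
  cat(sprintf("<icn_atlas> %d networks on a %s grid\n", length(x$networks),
              paste(x$grid$dim, collapse = "x")))
  for (nm in names(x$networks))
    cat(sprintf("  %-4s %d nodes\n", nm, nrow(x$networks[[nm]]$nodes)))
  invisible(x)
}

#' Network templates for component selection
#'
#' Spatial templates on the analysis grid, one per network, synthesised
#' from the atlas node tables. Provenance is recorded in the result.
#'
#' @param grid a `vox_grid`.
#' @param networks list of `network_spec`s; default all seven.
#' @param radius_mm node radius in mm.
#' @return named list of class `icn_templates`; each element is a list
#'   with `name`, `map` (3-D array) and `provenance`.
#' @export
make_templates <- function(grid = make_grid(), networks = default_networks(),
                           radius_mm = 8) {
  atlas <- make_network_atlas(networks, grid, radius_mm)
  out <- lapply(atlas$networks, function(nw) {
    prov <- if (nw$spec$name %in% c("AN", "CEN", "SMN"))
      "synthetic template (literature-typical peaks)"
    else "synthesised from group network peak table"
    list(name = nw$spec$name, map = nw$map, provenance = prov)
  })
  structure(out, class = "icn_templates", grid = grid)
}
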