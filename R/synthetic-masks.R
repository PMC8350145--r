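#' Specification of one synthetic subfield region
#'
#' Describes the shape of one label to be grown by [gen_subfield_mask].
#' Families are `blob` (near-spherical), `ribbon` (elongated, ~2.5:1 long
#' axis, emulating CA/SUB strips) and `sheet` (flat slab whose thickness
#' is `thickness_voxels`; note a thin sheet loses more than half its
#' voxels to one-voxel erosion and is therefore not part of the default
#' families). `attach_to` grows the region from the boundary of a
#' previously grown label (used to keep CA1/CA2/CA3 contiguous so the
#' pooled CA region erodes as one body).
#'
#' @param name subfield name (see [subfield_codes]).
#' @param target_voxels region size in voxels (>= 27).
#' @param shape_family `"blob"`, `"ribbon"` or `"sheet"`.
#' @param label_code integer label (> 0); defaults to the ASHS-style code.
#' @param thickness_voxels minimum thickness (>= 2 so a one-voxel erosion
#'   leaves a core); drives the minor axis for ribbon/sheet.
#' @param attach_to name of a previously listed spec, or NULL.
#' @return object of class `subfield_spec`.
#' @export
subfield_spec <- function(name, target_voxels, shape_family = "blob",
                          label_code = NULL, thickness_voxels = 8L,
                          attach_to = NULL) {
  if (is.null(label_code)) {
    codes <- subfield_codes()
    if (!name %in% names(codes))
      stop("no default label code for subfield ", name, call. = FALSE)
    label_code <- codes[[name]]
  }
  stopifnot(target_voxels >= 27, thickness_voxels >= 2, label_code > 0,
            shape_family %in% c("blob", "ribbon", "sheet"))
  structure(list(name = name, target_voxels = as.integer(target_voxels),
                 shape_family = shape_family,
                 label_code = as.integer(label_code),
                 thickness_voxels = as.integer(thickness_voxels),
                 attach_to = attach_to),
            class = "subfield_spec")
}

#' Default synthetic subfield specs for one hemisphere
#'
#' Sizes chosen so that every independently eroded unit (each standalone
#' label, and the contiguous CA1+CA2+CA3 chain that is pooled before
#' erosion) loses 20-50% of its voxels to a one-voxel erosion. Misc and
#' BA36 are generated so the exclusion pathway is exercised, but are
#' excluded from statistics.
#'
#' @param scale multiplies every `target_voxels` (used for reduced-size
#'   phantoms in simulation studies).
#' @param include_excluded include MISC and BA36 regions.
#' @return list of [subfield_spec].
#' @export
default_subfield_specs <- function(scale = 1, include_excluded = TRUE) {
  sc <- function(n) max(27L, as.integer(round(n * scale)))
  specs <- list(
    subfield_spec("DG",   sc(1200), "blob"),
    subfield_spec("CA1",  sc(1300), "ribbon", thickness_voxels = 9L),
    subfield_spec("CA2",  sc(300),  "blob", attach_to = "CA1"),
    subfield_spec("CA3",  sc(300),  "blob", attach_to = "CA2"),
    subfield_spec("SUB",  sc(1100), "ribbon", thickness_voxels = 9L),
    subfield_spec("EC",   sc(1000), "blob"),
    subfield_spec("BA35", sc(950),  "blob"))
  if (include_excluded) {
    specs <- c(specs, list(
      subfield_spec("BA36", sc(900), "blob"),
      subfield_spec("MISC", sc(700), "blob")))
  }
  specs
}

# semi-axes (voxels) of the growth ellipsoid for a spec
.spec_axes <- function(spec) {
  v <- spec$target_voxels
  switch(spec$shape_family,
    blob = {
      r <- (3 * v / (4 * pi))^(1 / 3)
      c(r, r, r)
    },
    ribbon = {
      # scale-free 2.5:1 elongation; minor radius never below the
      # requested half-thickness floor of 2.5 so an eroded core remains
      m <- max((3 * v / (4 * pi * 2.5))^(1 / 3), spec$thickness_voxels / 4, 2.5)
      c_ax <- 3 * v / (4 * pi * m^2)
      c(m, m, max(c_ax, m))
    },
    sheet = {
      h <- max(spec$thickness_voxels / 2, 1)
      a <- sqrt(3 * v / (4 * pi * h))
      c(a, a, h)
    })
}

#' Generate a synthetic subfield label mask
#'
#' Grows each spec as a jittered ellipsoid: voxels are ranked by
#' anisotropically weighted distance from the region centre plus a small
#' uniform jitter, and exactly `target_voxels` lowest-ranked free voxels
#' are taken. The jitter (< 1 voxel in distance units) roughens the
#' boundary while keeping the region 6-connected. Regions are placed on a
#' non-overlapping lattice of cells; `attach_to` specs grow from a seed on
#' the parent's boundary instead of their own cell.
#'
#' Unless `erosion_band` is NULL, the mask is checked (with internal
#' retries under a perturbed stream) so that the fraction of voxels
#' removed by [erode_labels] lies inside the band for every blob/ribbon
#' erosion unit (attachment chains are checked as their union, matching
#' the pooled-CA analysis path); sheets are exempt.
#'
#' @param grid_shape length-3 integer grid; NULL to auto-size.
#' @param specs list of [subfield_spec].
#' @param seed integer seed; identical inputs give bit-identical masks.
#' @param voxel_dims mm, length 3.
#' @param erosion_band numeric length 2 (default `c(0.20, 0.50)`) or NULL
#'   to skip the check (reduced-size phantoms).
#' @param jitter boundary roughness in distance units (0-1).
#' @return a [label_mask].
#' @export
gen_subfield_mask <- function(grid_shape = NULL, specs = default_subfield_specs(),
                              seed = 1L, voxel_dims = c(0.34, 0.34, 1.7),
                              erosion_band = c(0.20, 0.50), jitter = 0.5) {
  if (length(specs) == 0) {
    if (is.null(grid_shape)) grid_shape <- c(8L, 8L, 8L)
    return(label_mask(array(0L, grid_shape), voxel_dims = voxel_dims))
  }
  names(specs) <- vapply(specs, `[[`, character(1), "name")

  # cell sizing: an attached chain shares its root's cell
  root_of <- function(nm) {
    while (!is.null(specs[[nm]]$attach_to)) nm <- specs[[nm]]$attach_to
    nm
  }
  roots <- unique(vapply(names(specs), root_of, character(1)))
  chain_total <- vapply(roots, function(r) {
    sum(vapply(specs, function(s) {
      if (root_of(s$name) == r) s$target_voxels else 0L
    }, numeric(1)))
  }, numeric(1))
  cell_half <- vapply(roots, function(r) {
    ax <- .spec_axes(specs[[r]])
    grow <- (chain_total[r] / specs[[r]]$target_voxels)^(1 / 3)
    ceiling(ax * grow + 2.5)
  }, numeric(3))  # 3 x nroots
  hx <- max(cell_half[1, ]); hy <- max(cell_half[2, ]); hz <- max(cell_half[3, ])
  nroot <- length(roots)
  nx <- ceiling(sqrt(nroot)); ny <- ceiling(nroot / nx)
  need <- c(nx * (2 * hx + 1), ny * (2 * hy + 1), 2 * hz + 1)
  if (is.null(grid_shape)) grid_shape <- as.integer(need)
  grid_shape <- as.integer(grid_shape)
  need <- as.integer(need)
  if (any(grid_shape < need)) {
    big <- roots[which.max(colSums(cell_half))]
    stop(sprintf(
      "grid %s too small for specs (need >= %s; largest unit '%s')",
      paste(grid_shape, collapse = "x"), paste(need, collapse = "x"), big),
      call. = FALSE)
  }

  centres <- matrix(NA_real_, 3, nroot, dimnames = list(NULL, roots))
  for (i in seq_len(nroot)) {
    ix <- (i - 1) %% nx
    iy <- (i - 1) %/% nx
    centres[, i] <- c(ix * (2 * hx + 1) + hx + 1,
                      iy * (2 * hy + 1) + hy + 1,
                      grid_shape[3] / 2)
  }

  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }

  grow_once <- function(try_offset) {
    lab <- array(0L, grid_shape)
    nvox <- prod(grid_shape)
    coords <- arrayInd(seq_len(nvox), grid_shape)
    for (s in specs) {
      ax <- .spec_axes(s)
      if (is.null(s$attach_to)) {
        ctr <- centres[, root_of(s$name)] + stats::runif(3, -1, 1)
      } else {
        parent_code <- specs[[s$attach_to]]$label_code
        psel <- which(lab == parent_code)
        if (!length(psel)) stop("attach_to parent has no voxels", call. = FALSE)
        # boundary voxel of the parent farthest from the chain root centre
        pc <- coords[psel, , drop = FALSE]
        rc <- centres[, root_of(s$name)]
        far <- psel[which.max(colSums((t(pc) - rc)^2))]
        ctr <- coords[far, ] + 0.0
      }
      w <- ((coords[, 1] - ctr[1]) / ax[1])^2 +
           ((coords[, 2] - ctr[2]) / ax[2])^2 +
           ((coords[, 3] - ctr[3]) / ax[3])^2
      p <- sqrt(w) + jitter * stats::runif(nvox) / max(ax)
      p[lab != 0L] <- Inf
      ord <- order(p)[seq_len(s$target_voxels)]
      if (!is.finite(p[ord[s$target_voxels]]))
        stop(sprintf("grid too small: cannot place %d voxels for spec '%s'",
                     s$target_voxels, s$name), call. = FALSE)
      lab[ord] <- s$label_code
    }
    lab
  }

  band_ok <- function(lab) {
    if (is.null(erosion_band)) return(TRUE)
    units <- lapply(roots, function(r) {
      members <- Filter(function(s) root_of(s$name) == r, specs)
      list(fam = specs[[r]]$shape_family,
           codes = vapply(members, `[[`, integer(1), "label_code"))
    })
    merged <- lab
    for (u in units) merged[merged %in% u$codes] <- u$codes[1]
    m <- suppressWarnings(
      erode_labels(label_mask(merged,
                              label_table = stats::setNames(
                                vapply(units, function(u) u$codes[1], integer(1)),
                                roots),
                              voxel_dims = voxel_dims)))
    for (u in units) {
      if (u$fam == "sheet") next
      fr <- 1 - sum(m$labels == u$codes[1]) / sum(merged == u$codes[1])
      if (fr < erosion_band[1] || fr > erosion_band[2]) return(FALSE)
    }
    TRUE
  }

  auto_grid <- is.null(grid_shape) || all(grid_shape == need)
  lab <- NULL
  for (try in 0:4) {
    lab <- withr_seed(as.integer(seed) + 1000003L * try, grow_once(try))
    if (band_ok(lab)) break
    if (try == 4)
      warning("erosion fraction outside the target band after retries",
              call. = FALSE)
  }
  if (auto_grid && any(lab > 0L)) {
    # crop to the labelled bounding box (+1 voxel margin) so downstream
    # voxelwise passes do not pay for empty lattice cells
    idx <- which(lab > 0L)
    co <- arrayInd(idx, dim(lab))
    lo <- pmax(apply(co, 2, min) - 1L, 1L)
    hi <- pmin(apply(co, 2, max) + 1L, dim(lab))
    lab <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  tab <- subfield_codes()
  extra <- setdiff(vapply(specs, `[[`, integer(1), "label_code"), tab)
  if (length(extra)) {
    nm <- vapply(specs, `[[`, character(1), "name")[
      match(extra, vapply(specs, `[[`, integer(1), "label_code"))]
    tab <- c(tab, stats::setNames(as.integer(extra), nm))
  }
  label_mask(lab, label_table = tab, voxel_dims = voxel_dims)
}
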