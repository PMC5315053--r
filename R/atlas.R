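#' Region roles of the phantom atlas
#'
#' Integer label codes of the synthetic atlas regions: a ventral-ATL-like
#' semantic hub, an aSTG-like modality region, auditory and visual sensory
#' spokes, and white-matter / CSF nuisance compartments.
#'
#' @return Named integer vector mapping role name to label code
#'   (background = 0).
#' @export
atlas_roles <- function() {
  c(background = 0L, semantic_hub = 1L, modality_region = 2L,
    auditory_spoke = 3L, visual_spoke = 4L, white_matter = 5L, csf = 6L)
}

# squared mm distance of every grid voxel to a voxel-index centre
.dist2_to <- function(grid, centre_vox) {
  s <- grid$shape; vs <- grid$voxel_size
  dx <- ((seq_len(s[1]) - centre_vox[1]) * vs[1])^2
  dy <- ((seq_len(s[2]) - centre_vox[2]) * vs[2])^2
  dz <- ((seq_len(s[3]) - centre_vox[3]) * vs[3])^2
  outer(outer(dx, dy, "+"), dz, "+")
}

# take the n unlabelled voxels nearest to centre (ties broken by linear
# index, so the result is deterministic)
.grow_region <- function(d2, taken, n) {
  ord <- order(d2, seq_along(d2))
  free <- ord[!taken[ord]]
  if (length(free) < n) return(NULL)
  free[seq_len(n)]
}

#' Build the synthetic region atlas
#'
#' Places the gray-matter regions (semantic hub, modality region, two
#' sensory spokes) as compact balls inside a spherical "brain", and WM/CSF
#' compartments outside it, each with exactly the requested voxel count.
#' Construction is deterministic.
#'
#' @param config list with optional entries `shape` (default 28),
#'   `voxel_size` (default 2 mm), `brain_radius_mm` (default 16),
#'   `sizes` (named voxel counts; defaults semantic_hub 150,
#'   modality_region 150, auditory_spoke 80, visual_spoke 80,
#'   white_matter 200, csf 100).
#' @param seed integer; accepted for interface uniformity (construction is
#'   deterministic).
#' @return A `RegionAtlas`: list with `grid`, `labels` (3D integer),
#'   `brain_mask` (3D logical), `roles`, `sizes`, `centres` (voxel indices).
#' @export
make_phantom_atlas <- function(config = list(), seed = 1) {
  shape <- config$shape %||% 28L
  vs <- config$voxel_size %||% 2
  grid <- volume_grid(shape, vs)
  sizes <- utils::modifyList(
    list(semantic_hub = 150L, modality_region = 150L,
         auditory_spoke = 80L, visual_spoke = 80L,
         white_matter = 200L, csf = 100L),
    config$sizes %||% list())
  brain_r <- config$brain_radius_mm %||% 16
  s <- grid$shape
  centre <- (s + 1) / 2
  d2_centre <- .dist2_to(grid, centre)
  brain <- d2_centre <= brain_r^2

  # region centres, placed symmetrically well inside the brain ball and
  # outside it for the nuisance compartments
  off <- (brain_r * 0.55) / grid$voxel_size   # voxels
  centres <- list(
    semantic_hub    = centre + c(-off[1], -off[2], 0),
    modality_region = centre + c( off[1],  off[2], 0),
    auditory_spoke  = centre + c(-off[1],  off[2], 0),
    visual_spoke    = centre + c( off[1], -off[2], 0),
    white_matter    = centre + c(0, 0,  (brain_r + 4) / grid$voxel_size[3]),
    csf             = centre + c(0, 0, -(brain_r + 4) / grid$voxel_size[3]))

  labels <- array(0L, dim = s)
  taken <- array(FALSE, dim = s)
  roles <- atlas_roles()
  for (role in names(centres)) {
    n <- as.integer(sizes[[role]])
    if (n <= 0) next
    d2 <- .dist2_to(grid, centres[[role]])
    gray <- !(role %in% c("white_matter", "csf"))
    # gray regions must stay inside the brain ball, nuisance ones outside
    d2[if (gray) !brain else brain] <- Inf
    idx <- .grow_region(d2, taken, n)
    if (is.null(idx))
      stop(sprintf("cannot place %d voxels for region '%s' inside the grid; ",
                   n, role),
           "enlarge the grid or shrink the region sizes")
    labels[idx] <- roles[[role]]
    taken[idx] <- TRUE
  }
  brain_mask <- brain & !(labels %in% roles[c("white_matter", "csf")])
  dim(brain_mask) <- s
  structure(list(grid = grid, labels = labels, brain_mask = brain_mask,
                 roles = roles, sizes = sizes, centres = centres),
            class = "RegionAtlas")
}

#' Logical mask of one atlas region
#'
#' @param atlas a [make_phantom_atlas()] result.
#' @param role region role name (see [atlas_roles()]).
#' @return 3D logical array.
#' @export
region_mask <- function(atlas, role) {
  if (!role %in% names(atlas$roles)) stop("unknown region role: ", role)
  atlas$labels == atlas$roles[[role]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
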