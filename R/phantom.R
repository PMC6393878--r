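#' Ellipse parameters
#'
#' Parametric ellipse used both by the phantom generator and by the skull
#' detector. `rotation` is the angle (radians, in `[0, pi)`) of the
#' semi-major axis measured counter-clockwise from the column (x) axis in
#' image coordinates.
#'
#' @param center_row,center_col ellipse center in pixel coordinates.
#' @param semi_major,semi_minor semi-axes in pixels, `semi_major >= semi_minor > 0`.
#' @param rotation rotation angle in radians, reduced modulo `pi`.
#' @param votes accumulator support (filled in by [detect_skull_ellipse()]).
#' @return An object of class `ellipse_params`.
#' @export
ellipse_params <- function(center_row, center_col, semi_major, semi_minor,
                           rotation = 0, votes = NA_real_) {
  if (semi_minor <= 0 || semi_major < semi_minor)
    stop("require semi_major >= semi_minor > 0")
  structure(list(center_row = center_row, center_col = center_col,
                 semi_major = semi_major, semi_minor = semi_minor,
                 rotation = rotation %% pi, votes = votes),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse> center (%.1f, %.1f), semi-axes (%.1f, %.1f), rotation %.1f deg, votes %s\n",
    x$center_row, x$center_col, x$semi_major, x$semi_minor,
    x$rotation * 180 / pi, format(x$votes)))
  invisible(x)
}

#' Rasterize an ellipse interior as a binary mask
#'
#' A pixel is foreground iff its center (integer row/column coordinates)
#' satisfies the rotated-ellipse interior inequality
#' `(x'/a)^2 + (y'/b)^2 <= 1`.
#'
#' @param height,width image dimensions in pixels.
#' @param params an [ellipse_params].
#' @return Logical matrix. If the ellipse lies fully outside the image a
#'   warning is raised and an empty mask returned.
#' @export
make_ellipse_mask <- function(height, width, params) {
  stopifnot(inherits(params, "ellipse_params"))
  r <- matrix(seq_len(height), height, width) - params$center_row
  cc <- matrix(seq_len(width), height, width, byrow = TRUE) - params$center_col
  ct <- cos(params$rotation); st <- sin(params$rotation)
  xp <- cc * ct + r * st
  yp <- -cc * st + r * ct
  mask <- (xp / params$semi_major)^2 + (yp / params$semi_minor)^2 <= 1
  if (!any(mask)) warning("ellipse lies fully outside the image: empty mask")
  mask
}

#' Specification of a synthetic T1-like brain phantom
#'
#' The phantom emulates an axial T1-weighted slice as nested ellipses: a
#' bright skull ring, a dark CSF gap, a gray-matter annulus, a bright
#' white-matter core, and optionally a hyperintense tumor disk inside the
#' white matter. Intensities follow the T1 ordering (fat/white matter bright,
#' fluid dark): `wm > gm > csf >= background`.
#'
#' @param height,width image size in pixels.
#' @param skull [ellipse_params] of the outer skull outline.
#' @param skull_thickness,csf_gap,gm_thickness radial extents in pixels of
#'   the skull ring, CSF gap and gray-matter annulus.
#' @param intensities named numeric vector with entries `background`, `csf`,
#'   `gm`, `wm`, `skull`, `tumor`, all in `[0, 1]`.
#' @param noise_sigma standard deviation of additive Gaussian noise (image is
#'   clipped to `[0, 1]` afterwards).
#' @param tumor `NULL` or `list(center_row=, center_col=, radius=)`.
#' @param seed integer RNG seed making the phantom deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         skull = ellipse_params(128, 128, 110, 90),
                         skull_thickness = 6, csf_gap = 8, gm_thickness = 18,
                         intensities = c(background = 0.00, csf = 0.15,
                                         gm = 0.45, wm = 0.80, skull = 0.95,
                                         tumor = 0.90),
                         noise_sigma = 0, tumor = NULL, seed = 0L) {
  need <- c("background", "csf", "gm", "wm", "skull", "tumor")
  if (!all(need %in% names(intensities)))
    stop("intensities must name: ", paste(need, collapse = ", "))
  i <- intensities
  if (!(i["wm"] > i["gm"] && i["gm"] > i["csf"] && i["csf"] >= i["background"]))
    stop("T1 ordering violated: need wm > gm > csf >= background")
  if (any(i < 0 | i > 1)) stop("intensities must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  depth <- skull_thickness + csf_gap + gm_thickness + 2
  if (skull$semi_minor <= depth || skull$semi_major <= depth)
    .stop_neuroseg("infeasible nesting: skull semi-axes must exceed skull_thickness + csf_gap + gm_thickness + 2",
                   "neuroseg_geometry_error")
  structure(list(height = as.integer(height), width = as.integer(width),
                 skull = skull, skull_thickness = skull_thickness,
                 csf_gap = csf_gap, gm_thickness = gm_thickness,
                 intensities = i, noise_sigma = noise_sigma,
                 tumor = tumor, seed = as.integer(seed)),
            class = "phantom_spec")
}

.shrunk_ellipse <- function(e, d) {
  ellipse_params(e$center_row, e$center_col, e$semi_major - d,
                 e$semi_minor - d, e$rotation)
}

#' Generate a synthetic brain slice with exact ground truth
#'
#' Renders the piecewise-constant phantom described by a [phantom_spec],
#' adds clipped Gaussian noise, and returns both the noisy slice and the
#' exact generating tissue masks. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `slice` (a [grayscale_slice]), `truth` (a
#'   list of pairwise-disjoint logical masks `gm_mask`, `wm_mask`,
#'   `csf_mask`, `skull_mask`, and `tumor_mask` or `NULL`), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  e_outer <- spec$skull
  e_skull_in <- .shrunk_ellipse(e_outer, spec$skull_thickness)
  e_csf_in <- .shrunk_ellipse(e_outer, spec$skull_thickness + spec$csf_gap)
  e_gm_in <- .shrunk_ellipse(e_outer, spec$skull_thickness + spec$csf_gap +
                               spec$gm_thickness)
  m_outer <- make_ellipse_mask(h, w, e_outer)
  m_skull_in <- make_ellipse_mask(h, w, e_skull_in)
  m_csf_in <- make_ellipse_mask(h, w, e_csf_in)
  m_gm_in <- make_ellipse_mask(h, w, e_gm_in)
  skull_mask <- m_outer & !m_skull_in
  csf_mask <- m_skull_in & !m_csf_in
  gm_mask <- m_csf_in & !m_gm_in
  wm_mask <- m_gm_in
  tumor_mask <- NULL
  if (!is.null(spec$tumor)) {
    tu <- spec$tumor
    tumor_mask <- make_ellipse_mask(h, w, ellipse_params(
      tu$center_row, tu$center_col, tu$radius, tu$radius))
    tumor_mask <- tumor_mask & m_gm_in  # keep the blob inside the WM core
    wm_mask <- wm_mask & !tumor_mask
  }
  i <- spec$intensities
  img <- matrix(i[["background"]], h, w)
  img[csf_mask] <- i[["csf"]]
  img[gm_mask] <- i[["gm"]]
  img[wm_mask] <- i[["wm"]]
  img[skull_mask] <- i[["skull"]]
  if (!is.null(tumor_mask)) img[tumor_mask] <- i[["tumor"]]
  if (spec$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    img <- img + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w)
    img <- pmin(pmax(img, 0), 1)
  }
  list(slice = grayscale_slice(img, source_format = "PHANTOM",
                               intensity_max = 1),
       truth = list(gm_mask = gm_mask, wm_mask = wm_mask,
                    csf_mask = csf_mask, skull_mask = skull_mask,
                    tumor_mask = tumor_mask),
       spec = spec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
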