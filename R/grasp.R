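#' Cup geometry and mass specification
#'
#' Describes a conical-frustum drinking cup and its optional liquid content.
#' Defaults are the study cup: 114 mm tall, 57 mm outer diameter at the base
#' and 87 mm at the top, 11 g empty; the filled cup weighs 252 g in total, so
#' the liquid contributes 241 g. The liquid column height is an explicit
#' input (default 82 mm): it is not printed anywhere and cannot be recovered
#' from the liquid mass without knowing its density and the wall geometry, so
#' it is treated as data (see the methods vignette).
#'
#' @param h_cup Cup height in mm.
#' @param r1 Radius at the base (smaller end) in mm.
#' @param r2 Radius at the top in mm.
#' @param m_cup Cup mass in g.
#' @param liquid `NULL` for an empty cup, or a list with `h_liquid` (mm) and
#'   `m_liquid` (g).
#' @param base_z Vertical coordinate of the cup base in the trial frame (mm).
#' @return A `cup_spec` list.
#' @export
cup_spec <- function(h_cup = 114, r1 = 28.5, r2 = 43.5, m_cup = 11,
                     liquid = NULL, base_z = 0) {
  if (h_cup <= 0 || r1 <= 0 || r2 <= 0) {
    stop("cup height and radii must be positive", call. = FALSE)
  }
  if (m_cup < 0) stop("masses must be non-negative", call. = FALSE)
  if (!is.null(liquid)) {
    if (is.null(liquid$h_liquid) || is.null(liquid$m_liquid)) {
      stop("liquid must provide h_liquid and m_liquid", call. = FALSE)
    }
    if (liquid$h_liquid <= 0 || liquid$h_liquid > h_cup) {
      stop("liquid height must lie in (0, h_cup]", call. = FALSE)
    }
    if (liquid$m_liquid < 0) stop("masses must be non-negative", call. = FALSE)
  }
  structure(list(h_cup = h_cup, r1 = r1, r2 = r2, m_cup = m_cup,
                 liquid = liquid, base_z = base_z),
            class = "cup_spec")
}

#' The filled study cup
#'
#' Convenience constructor: the default cup of [cup_spec()] with 241 g of
#' liquid standing 82 mm high.
#'
#' @param base_z Vertical coordinate of the cup base (mm).
#' @return A `cup_spec`.
#' @export
cup_spec_filled <- function(base_z = 0) {
  cup_spec(liquid = list(h_liquid = 82, m_liquid = 241), base_z = base_z)
}

#' Centroid of a solid conical frustum
#'
#' Height of the centre of mass of a solid frustum above its base (the end
#' with radius `r1`):
#' \deqn{COM = \frac{h (r_1^2 + 2 r_1 r_2 + 3 r_2^2)}{4 (r_1^2 + r_1 r_2 + r_2^2)}}
#' Limiting cases: a cylinder (`r1 == r2`) gives `h/2`; a cone with its apex
#' at the base (`r1 == 0`) gives `0.75 h`.
#'
#' @param h Frustum height (mm), > 0.
#' @param r1 Radius at the base (mm), >= 0.
#' @param r2 Radius at the top (mm), >= 0. Not both radii may be zero.
#' @return Centroid height above the base in mm. Vectorised over all three
#'   arguments.
#' @export
frustum_centroid <- function(h, r1, r2) {
  if (any(h <= 0)) stop("frustum height must be positive", call. = FALSE)
  if (any(r1 < 0 | r2 < 0) || any(r1 == 0 & r2 == 0)) {
    stop("radii must be non-negative and not both zero", call. = FALSE)
  }
  h * (r1^2 + 2 * r1 * r2 + 3 * r2^2) / (4 * (r1^2 + r1 * r2 + r2^2))
}

#' Mass-weighted centre of mass of cup plus liquid
#'
#' Combines the component centroids by their masses:
#' \deqn{COM_{weight} = \frac{L_w COM_{liquid} + C_w COM_{cup}}{L_w + C_w}}
#' With zero liquid mass the cup centroid is returned exactly.
#'
#' @param com_cup Cup centroid height above the base (mm).
#' @param m_cup Cup mass (g).
#' @param com_liquid Liquid centroid height above the base (mm).
#' @param m_liquid Liquid mass (g).
#' @return Combined centre of mass in mm above the base.
#' @export
combined_com <- function(com_cup, m_cup, com_liquid = 0, m_liquid = 0) {
  if (any(m_cup + m_liquid <= 0)) {
    stop("total mass must be positive", call. = FALSE)
  }
  ifelse(m_liquid == 0, com_cup,
         (m_liquid * com_liquid + m_cup * com_cup) / (m_liquid + m_cup))
}

#' Centre of mass of a cup specification
#'
#' Applies [frustum_centroid()] to the cup (and, when present, the liquid
#' column, using the same radii taper truncated at the liquid height) and
#' combines the two with [combined_com()]. With the default geometry this
#' yields 64.8 mm (printed as 65 mm) empty and 46.2 mm (printed as 46 mm)
#' filled.
#'
#' @param cup A [cup_spec()].
#' @return COM height above the cup base in mm.
#' @export
cup_com <- function(cup) {
  stopifnot(inherits(cup, "cup_spec"))
  com_cup <- frustum_centroid(cup$h_cup, cup$r1, cup$r2)
  if (is.null(cup$liquid)) return(com_cup)
  hl <- cup$liquid$h_liquid
  r_top <- cup$r1 + (cup$r2 - cup$r1) * hl / cup$h_cup
  com_liq <- frustum_centroid(hl, cup$r1, r_top)
  combined_com(com_cup, cup$m_cup, com_liq, cup$liquid$m_liquid)
}

#' Thumb-index aperture series
#'
#' Per-sample 3-D Euclidean distance between the thumb and index fingertips
#' over a window — the grip aperture, whose maximum before object contact is
#' the maximum grip aperture (MGA).
#'
#' @param thumb,index [marker_trajectory()] objects on a shared time base.
#' @param window Integer vector of sample indices (default: all samples).
#'   Must be gap-free in both trajectories.
#' @return Numeric vector of apertures (mm), one per window sample.
#' @export
aperture_series <- function(thumb, index, window = NULL) {
  n <- length(thumb)
  if (length(index) != n) {
    stop("thumb and index trajectories differ in length", call. = FALSE)
  }
  if (is.null(window)) window <- seq_len(n)
  if (any(window < 1L | window > n)) {
    stop("window outside trajectory extent", call. = FALSE)
  }
  d <- thumb$positions[window, , drop = FALSE] -
    index$positions[window, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Maximum grip aperture and its timing
#'
#' The MGA is the maximum thumb-index distance during the reach, before
#' object contact. Its timing is reported both absolutely (ms from reach
#' onset) and relative to the reach duration (%), the form in which grasp
#' preparation differences between object properties typically appear. Ties
#' are broken by the earliest sample.
#'
#' @param aperture Aperture series over the reach window
#'   `[onset, offset)`, as from [aperture_series()].
#' @param reach One-row tibble for the reach segment (needs `onset`,
#'   `offset`).
#' @param sample_rate Sampling rate in Hz.
#' @return Tibble with `mga` (mm), `mga_time_abs` (ms) and `mga_time_rel`
#'   (% of reach duration).
#' @export
mga_features <- function(aperture, reach, sample_rate) {
  if (length(aperture) == 0) stop("empty aperture window", call. = FALSE)
  n_span <- reach$offset - reach$onset
  if (length(aperture) != n_span) {
    stop("aperture must cover exactly [onset, offset)", call. = FALSE)
  }
  period <- 1000 / sample_rate
  i <- which.max(aperture)  # earliest on ties
  duration <- n_span * period
  tibble::new_tibble(list(
    mga = aperture[i],
    mga_time_abs = (i - 1L) * period,
    mga_time_rel = 100 * (i - 1L) * period / duration
  ), nrow = 1L)
}

#' Spatial grasp features: grip centre, COM and signed deviation
#'
#' At the contact instant — the reach offset sample, where the hand speed
#' re-crosses the segmentation threshold — the grip centre is the mean of the
#' three fingertip z-coordinates. The signed grip deviation is its vertical
#' distance from the object's centre of mass: positive above the COM,
#' negative below.
#'
#' @param thumb,index,middle [marker_trajectory()] objects on a shared time
#'   base.
#' @param contact_idx Contact sample index (the reach offset).
#' @param cup A [cup_spec()] describing the grasped object, including
#'   `base_z`.
#' @return Tibble with `grip_center_z` (mm, world frame), `com` (mm above the
#'   cup base) and `grip_deviation` (mm, signed).
#' @export
grip_features <- function(thumb, index, middle, contact_idx, cup) {
  stopifnot(inherits(cup, "cup_spec"))
  n <- length(thumb)
  if (contact_idx < 1L || contact_idx > n) {
    stop("contact index outside trajectory extent", call. = FALSE)
  }
  if (!thumb$valid[contact_idx] || !index$valid[contact_idx] ||
      !middle$valid[contact_idx]) {
    stop("invalid fingertip sample at contact; refusing to impute at the ",
         "measurement instant", call. = FALSE)
  }
  gz <- unname(thumb$positions[contact_idx, 3] +
                 index$positions[contact_idx, 3] +
                 middle$positions[contact_idx, 3]) / 3
  com <- cup_com(cup)
  tibble::new_tibble(list(
    grip_center_z = gz,
    com = com,
    grip_deviation = gz - (cup$base_z + com)
  ), nrow = 1L)
}
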