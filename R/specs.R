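#' Parametric directional DBS lead geometry
#'
#' Describes an 8-contact directional lead: one tip contact, two rows of
#' three 90-degree segmented contacts, and one full cylindrical ring
#' contact, mounted on an insulating shaft. All lengths are in millimetres,
#' angles in degrees. The lead axis is +z with the tip at the origin;
#' the row-1 segment "a" is centered at azimuth 0 (right-handed).
#'
#' @param lead_radius Outer radius of the lead body (mm).
#' @param tip_contact_length Axial length of the tip contact band (mm).
#' @param ring_contact_length Axial length of ring and directional contact
#'   bands (mm).
#' @param inter_contact_gap Axial gap between successive contact bands (mm).
#' @param segment_arc Azimuthal arc of one directional segment (degrees).
#' @param segments_per_row Number of directional segments per row (3).
#' @param n_rows Number of directional rows (2).
#' @param contact_thickness Radial depth of explicitly modeled contact
#'   domains (mm); explicit contacts are thin conductor shells on the lead
#'   surface.
#' @param shaft_length Shaft length modeled above the topmost contact (mm);
#'   the shaft exits through the top of the tissue domain.
#' @return An object of class `lead_spec`.
#' @examples
#' lead <- lead_spec()
#' contact_layout(lead)
#' @export
lead_spec <- function(lead_radius = 0.65,
                      tip_contact_length = 1.5,
                      ring_contact_length = 1.5,
                      inter_contact_gap = 0.5,
                      segment_arc = 90,
                      segments_per_row = 3,
                      n_rows = 2,
                      contact_thickness = 0.1,
                      shaft_length = 40) {
  lens <- c(lead_radius = lead_radius, tip_contact_length = tip_contact_length,
            ring_contact_length = ring_contact_length,
            inter_contact_gap = inter_contact_gap,
            contact_thickness = contact_thickness, shaft_length = shaft_length)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lead lengths must be positive and finite")
  if (segments_per_row != 3L || n_rows != 2L)
    stop("the directional lead has 3 segments per row and 2 rows ",
         "(8 contacts total: tip + 6 directional + ring)")
  if (segment_arc * segments_per_row >= 360)
    stop("segment_arc * segments_per_row must be < 360 degrees ",
         "(gaps between segments must be nonzero)")
  if (contact_thickness >= lead_radius)
    stop("contact_thickness must be smaller than lead_radius")
  out <- list(lead_radius = lead_radius,
              tip_contact_length = tip_contact_length,
              ring_contact_length = ring_contact_length,
              inter_contact_gap = inter_contact_gap,
              segment_arc = segment_arc,
              segments_per_row = as.integer(segments_per_row),
              n_rows = as.integer(n_rows),
              contact_thickness = contact_thickness,
              shaft_length = shaft_length)
  class(out) <- "lead_spec"
  out
}

#' @export
print.lead_spec <- function(x, ...) {
  cat("Directional DBS lead (8 contacts)\n")
  cat(sprintf("  radius %.3g mm, contact lengths %.3g/%.3g mm, gap %.3g mm\n",
              x$lead_radius, x$tip_contact_length, x$ring_contact_length,
              x$inter_contact_gap))
  cat(sprintf("  %d x %d directional segments, %.3g deg arc, shell %.3g mm\n",
              x$n_rows, x$segments_per_row, x$segment_arc,
              x$contact_thickness))
  invisible(x)
}

#' Contact bands and azimuths of a directional lead
#'
#' Tabulates, for each of the 8 contacts, its axial band, azimuth center
#' (NA for full-circumference bands) and type. Contact ids: 1 = tip,
#' 2-4 = row-1 segments a/b/c, 5-7 = row-2 segments a/b/c, 8 = ring.
#'
#' @param lead A [lead_spec()].
#' @return A data.frame with one row per contact.
#' @export
contact_layout <- function(lead) {
  stopifnot(inherits(lead, "lead_spec"))
  g <- lead$inter_contact_gap
  z0 <- c(0,
          lead$tip_contact_length + g,
          lead$tip_contact_length + 2 * g + lead$ring_contact_length,
          lead$tip_contact_length + 3 * g + 2 * lead$ring_contact_length)
  z1 <- z0 + c(lead$tip_contact_length, rep(lead$ring_contact_length, 3))
  az <- seq(0, 360, length.out = lead$segments_per_row + 1L)[
    seq_len(lead$segments_per_row)]
  data.frame(
    contact = 1:8,
    label = c("tip", "d1a", "d1b", "d1c", "d2a", "d2b", "d2c", "ring"),
    type = c("tip", rep("directional", 6), "cylinder"),
    z0 = c(z0[1], rep(z0[2], 3), rep(z0[3], 3), z1[4] - lead$ring_contact_length),
    z1 = c(z1[1], rep(z1[2], 3), rep(z1[3], 3), z1[4]),
    azimuth = c(NA, az, az, NA),
    stringsAsFactors = FALSE)
}

#' Resolve a contact identifier
#'
#' Accepts an integer 1-8 or a label (`"tip"`, `"d1a"`..`"d2c"`, `"ring"`;
#' also `"cylinder"` for the ring).
#' @param contact Integer or character contact identifier.
#' @return Integer contact id in 1..8.
#' @export
contact_id <- function(contact) {
  labs <- c("tip", "d1a", "d1b", "d1c", "d2a", "d2b", "d2c", "ring")
  if (is.character(contact)) {
    if (identical(contact, "cylinder")) contact <- "ring"
    i <- match(contact, labs)
    if (is.na(i)) stop("unknown contact label: ", contact)
    return(as.integer(i))
  }
  contact <- as.integer(contact)
  if (length(contact) != 1L || is.na(contact) || contact < 1L || contact > 8L)
    stop("contact id must be in 1..8")
  contact
}

#' Simplified tissue domain around the lead
#'
#' The lead sits in a bounded homogeneous brain domain: a 0.5 mm
#' encapsulation sheath around the full lead, surrounded by brain tissue out
#' to a distant boundary that is insulated except for a grounded patch on
#' the face opposite the lead tip.
#'
#' @param encapsulation_thickness Encapsulation sheath thickness (mm).
#' @param brain_radius Radius of the bounded brain domain (mm); must be at
#'   least 25 lead radii so the grounded boundary is far-field.
#' @param ground_radius Radius of the grounded patch on the bottom face (mm).
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(encapsulation_thickness = 0.5,
                        brain_radius = 50,
                        ground_radius = 10) {
  stopifnot(encapsulation_thickness > 0, brain_radius > 0, ground_radius > 0,
            ground_radius < brain_radius)
  out <- list(encapsulation_thickness = encapsulation_thickness,
              brain_radius = brain_radius,
              ground_radius = ground_radius)
  class(out) <- "domain_spec"
  out
}

#' Tissue and lead conductivities
#'
#' Isotropic conductivities (S/m) per region: brain 0.2, encapsulation 0.13,
#' explicit platinum/iridium contact 5.3e6, explicit insulating shaft 1e-16.
#'
#' @param brain,encapsulation,contact,shaft Conductivities in S/m.
#' @return An object of class `conductivity_map`.
#' @export
conductivity_map <- function(brain = 0.2, encapsulation = 0.13,
                             contact = 5.3e6, shaft = 1e-16) {
  v <- c(brain = brain, encapsulation = encapsulation,
         contact = contact, shaft = shaft)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all conductivities must be positive and finite")
  structure(as.list(v), class = "conductivity_map")
}

#' The 15-variant volume-conductor model matrix
#'
#' Enumerates the admissible combinations of current source and geometry
#' representation: five current sources for the active contact, each with
#' the subset of explicit/boundary representations of the active contact,
#' inactive contacts, and shaft that the source admits (a current density
#' source needs a boundary active contact; point and boundary current
#' sources need an explicit one). Inactive contacts in boundary
#' representation are floating equipotential conductors with zero net
#' current; explicit inactive contacts are platinum domains.
#'
#' @return A data.frame with columns `model_id`, `source_type`,
#'   `active_contact_rep`, `inactive_contacts_rep`, `shaft_rep`.
#' @export
variant_table <- function() {
  src <- c(rep("point_current", 3), rep("boundary_current", 3),
           "current_density", rep("electric_potential", 4),
           rep("floating_potential", 4))
  eee <- rbind(c("explicit", "explicit", "explicit"),
               c("explicit", "explicit", "boundary"),
               c("explicit", "boundary", "boundary"))
  bbb <- c("boundary", "boundary", "boundary")
  geo <- rbind(eee, eee, bbb, eee, bbb, eee, bbb)
  data.frame(model_id = 1:15,
             source_type = src,
             active_contact_rep = geo[, 1],
             inactive_contacts_rep = geo[, 2],
             shaft_rep = geo[, 3],
             stringsAsFactors = FALSE)
}

#' One volume-conductor model variant
#'
#' Either give `model_id` (1-15) or the full combination of `source_type`
#' and geometry representations; combinations outside the model matrix
#' ([variant_table()]) are rejected with the violated constraint.
#'
#' @param model_id Integer 1-15, a row of [variant_table()].
#' @param source_type One of `"point_current"`, `"boundary_current"`,
#'   `"current_density"`, `"electric_potential"`, `"floating_potential"`.
#' @param active_contact_rep,inactive_contacts_rep,shaft_rep `"explicit"` or
#'   `"boundary"`.
#' @param active_contact Active contact id or label (see [contact_id()]);
#'   default is the row-1 directional segment at azimuth 0.
#' @return An object of class `variant_spec`.
#' @examples
#' variant_spec(1)
#' variant_spec(source_type = "floating_potential",
#'              active_contact_rep = "boundary",
#'              inactive_contacts_rep = "boundary", shaft_rep = "boundary")
#' @export
variant_spec <- function(model_id = NULL, source_type = NULL,
                         active_contact_rep = NULL,
                         inactive_contacts_rep = NULL,
                         shaft_rep = NULL,
                         active_contact = "d1a") {
  tab <- variant_table()
  if (!is.null(model_id)) {
    model_id <- as.integer(model_id)
    if (is.na(model_id) || model_id < 1L || model_id > 15L)
      stop("model_id must be an integer in 1..15")
    row <- tab[tab$model_id == model_id, ]
    if (!is.null(source_type) && source_type != row$source_type)
      stop("source_type does not match model_id ", model_id)
  } else {
    source_type <- match.arg(source_type, unique(tab$source_type))
    active_contact_rep <- match.arg(active_contact_rep,
                                    c("explicit", "boundary"))
    inactive_contacts_rep <- match.arg(inactive_contacts_rep,
                                       c("explicit", "boundary"))
    shaft_rep <- match.arg(shaft_rep, c("explicit", "boundary"))
    hit <- tab$source_type == source_type &
      tab$active_contact_rep == active_contact_rep &
      tab$inactive_contacts_rep == inactive_contacts_rep &
      tab$shaft_rep == shaft_rep
    if (!any(hit)) {
      # name the violated constraint
      if (source_type == "current_density" && active_contact_rep == "explicit")
        stop("invalid variant: a current density source applies only to ",
             "exterior boundaries, so the active contact must be 'boundary'")
      if (source_type %in% c("point_current", "boundary_current") &&
          active_contact_rep == "boundary")
        stop("invalid variant: ", source_type, " requires an explicit ",
             "active contact domain")
      stop("invalid variant: the combination (", source_type, ", ",
           active_contact_rep, ", ", inactive_contacts_rep, ", ", shaft_rep,
           ") is not a row of the model matrix; see variant_table()")
    }
    row <- tab[hit, ]
  }
  out <- list(model_id = row$model_id,
              source_type = row$source_type,
              active_contact_rep = row$active_contact_rep,
              inactive_contacts_rep = row$inactive_contacts_rep,
              shaft_rep = row$shaft_rep,
              active_contact = contact_id(active_contact))
  class(out) <- "variant_spec"
  out
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("VC model variant #%d: %s source\n", x$model_id, x$source_type))
  cat(sprintf("  active contact %d (%s), inactive %s, shaft %s\n",
              x$active_contact, x$active_contact_rep,
              x$inactive_contacts_rep, x$shaft_rep))
  invisible(x)
}

#' Stimulus waveform
#'
#' Monophasic rectangular current pulse. The waveform takes values in
#' \{0, 1\} and is scaled by the (cathodic) stimulus amplitude in mA.
#'
#' @param pulse_width Pulse width in microseconds.
#' @param amplitude Stimulus amplitude magnitude in mA (cathodic).
#' @param onset_delay Delay before pulse onset (us).
#' @param t_total Total simulated time (ms).
#' @param shape Only `"monophasic_rectangular"` is supported.
#' @return An object of class `stimulus_waveform`.
#' @export
stimulus_waveform <- function(pulse_width = 60, amplitude = 1,
                              onset_delay = 100, t_total = 3,
                              shape = "monophasic_rectangular") {
  shape <- match.arg(shape)
  stopifnot(pulse_width > 0, amplitude >= 0, onset_delay >= 0, t_total > 0)
  if ((onset_delay + pulse_width) / 1000 >= t_total)
    stop("pulse must end before t_total")
  structure(list(shape = shape, pulse_width = pulse_width,
                 amplitude = amplitude, onset_delay = onset_delay,
                 t_total = t_total),
            class = "stimulus_waveform")
}
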