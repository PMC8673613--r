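test_that("the variant matrix has exactly 15 admissible rows and all other combinations are rejected", {
  tab <- variant_table()
  expect_equal(nrow(tab), 15L)
  expect_equal(tab$model_id, 1:15)
  # every listed row is constructible
  for (i in 1:15) {
    v <- variant_spec(i)
    expect_s3_class(v, "variant_spec")
    expect_identical(v$model_id, i)
  }
  # enumerate the full 5 x 2 x 2 x 2 combination space: exactly the 15
  # table rows construct, everything else errors
  srcs <- unique(tab$source_type)
  reps <- c("explicit", "boundary")
  n_ok <- 0L
  for (s in srcs) for (a in reps) for (ia in reps) for (sh in reps) {
    in_tab <- any(tab$source_type == s & tab$active_contact_rep == a &
                    tab$inactive_contacts_rep == ia & tab$shaft_rep == sh)
    if (in_tab) {
      expect_s3_class(variant_spec(source_type = s, active_contact_rep = a,
                                   inactive_contacts_rep = ia,
                                   shaft_rep = sh), "variant_spec")
      n_ok <- n_ok + 1L
    } else {
      expect_error(variant_spec(source_type = s, active_contact_rep = a,
                                inactive_contacts_rep = ia, shaft_rep = sh),
                   "invalid variant")
    }
  }
  expect_equal(n_ok, 15L)
})

test_that("source/geometry constraints are named in rejections", {
  expect_error(variant_spec(source_type = "current_density",
                            active_contact_rep = "explicit",
                            inactive_contacts_rep = "boundary",
                            shaft_rep = "boundary"),
               "exterior boundaries")
  expect_error(variant_spec(source_type = "point_current",
                            active_contact_rep = "boundary",
                            inactive_contacts_rep = "boundary",
                            shaft_rep = "boundary"),
               "explicit")
})

test_that("lead and domain specifications validate their invariants", {
  lead <- lead_spec()
  lay <- contact_layout(lead)
  expect_equal(nrow(lay), 8L)
  expect_equal(sum(lay$type == "directional"), 6L)
  expect_error(lead_spec(lead_radius = -1), "positive")
  expect_error(lead_spec(segment_arc = 120), "360")
  expect_error(lead_spec(segments_per_row = 4), "8 contacts")
  expect_error(lead_spec(contact_thickness = 0.7), "smaller than lead_radius")
  expect_error(domain_spec(brain_radius = -5))
  expect_error(conductivity_map(brain = 0), "positive")
  # default conductivities
  cm <- conductivity_map()
  expect_equal(cm$brain, 0.2)
  expect_equal(cm$encapsulation, 0.13)
  expect_equal(cm$contact, 5.3e6)
  expect_equal(cm$shaft, 1e-16)
})

test_that("contact ids resolve from labels and integers", {
  expect_equal(contact_id("tip"), 1L)
  expect_equal(contact_id("d1a"), 2L)
  expect_equal(contact_id("cylinder"), 8L)
  expect_equal(contact_id(5), 5L)
  expect_error(contact_id("d9x"), "unknown")
  expect_error(contact_id(9), "1..8")
})

test_that("directional contact centers sit on the lead surface at the segment azimuth", {
  lead <- lead_spec()
  ctr <- contact_center(lead, "d1a")
  expect_equal(ctr[1], lead$lead_radius)
  expect_equal(ctr[2], 0)
  ctr2 <- contact_center(lead, "d1b")
  expect_equal(atan2(ctr2[2], ctr2[1]) * 180 / pi, 120)
  expect_equal(contact_center(lead, "tip")[1:2], c(0, 0))
})
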