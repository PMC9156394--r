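# local brute-force simplicity oracle (pairwise segment intersections)
polygon_simple_for_test <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1 else i + 1, ])
  inter <- function(p, q) {
    d1 <- q[2, ] - q[1, ]; d2 <- p[2, ] - p[1, ]
    cr <- function(a, b) a[1] * b[2] - a[2] * b[1]
    t1 <- cr(d1, p[1, ] - q[1, ]); t2 <- cr(d1, p[2, ] - q[1, ])
    t3 <- cr(d2, q[1, ] - p[1, ]); t4 <- cr(d2, q[2, ] - p[1, ])
    (t1 * t2 < 0) && (t3 * t4 < 0)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j == i + 1 || (i == 1 && j == n)) next
    if (inter(seg(i), seg(j))) return(FALSE)
  }
  TRUE
}


test_that("degenerate geometry inputs are rejected", {
  v <- study_vessels()
  expect_error(anastomosis_geometry(v$donor, v$graft, 0, 100e-3),
               "degenerate")
  expect_error(anastomosis_geometry(v$donor, v$graft, -15, 100e-3),
               "degenerate")
  expect_error(anastomosis_geometry(v$donor, v$graft, 95, 100e-3),
               "degenerate")
  expect_error(anastomosis_geometry(v$donor, v$graft, 45, 0), "junction_offset")
  expect_error(anastomosis_geometry(v$donor, v$graft, 45, 0.2), "junction_offset")
  expect_error(vessel_spec(-1e-3), "internal_diameter")
  expect_error(vessel_spec(2.3e-3, 0, 10e-3), "10 internal diameters")
  expect_error(domain_truncation(3, 15, 15), ">= 5")
})

test_that("junction opening width follows the chord-length law d/sin(theta)", {
  for (a in c(30, 45, 60, 75, 90)) {
    ol <- build_outline(study_geometry(a))
    w_measured <- ol$params$toe[1] - ol$params$heel[1]
    w_expected <- 2.3e-3 / sin(a * pi / 180)
    expect_lt(abs(w_measured - w_expected) / w_expected, 1e-9)
    expect_true(polygon_simple_for_test(ol$vertices))
  }
  # 90 degrees, equal diameters: opening equals graft diameter and the
  # graft axis is perpendicular to the donor axis
  ol90 <- build_outline(study_geometry(90))
  expect_equal(ol90$params$opening_width, 2.3e-3, tolerance = 1e-12)
  expect_equal(ol90$params$e, c(0, 1), tolerance = 1e-12)
})

test_that("outline records landmarks and patch runs", {
  ol <- build_outline(study_geometry(45))
  expect_named(ol$landmarks, c("heel", "toe", "hood", "floor"),
               ignore.order = TRUE)
  d <- 2.3e-3
  expect_equal(unname(ol$landmarks$heel[2]), d)
  expect_equal(unname(ol$landmarks$toe[2]), d)
  expect_equal(unname(ol$landmarks$floor[2]), 0)
  expect_gt(ol$landmarks$hood[2], d)       # hood sits up the graft wall
  expect_equal(sum(ol$edge_patch == "inlet"), 1L)
  expect_equal(sum(ol$edge_patch == "outlet_donor"), 1L)
  expect_equal(sum(ol$edge_patch == "outlet_graft"), 1L)
  expect_true(all(ol$edge_patch %in%
                  c("inlet", "outlet_donor", "outlet_graft", "wall")))
})

test_that("outline depends only on relative junction placement", {
  v <- study_vessels()
  g1 <- anastomosis_geometry(v$donor, v$graft, 60, 100e-3)
  g2 <- anastomosis_geometry(v$donor, v$graft, 60, 120e-3)
  tr <- domain_truncation(10, 10, 10)
  expect_equal(build_outline(g1, tr)$vertices, build_outline(g2, tr)$vertices)
})

test_that("truncation overrunning the physical vessels raises domain errors", {
  v <- study_vessels()
  # junction very close to the donor inlet: upstream run does not fit
  g <- anastomosis_geometry(v$donor, v$graft, 60, 20e-3)
  expect_error(build_outline(g, domain_truncation(15, 15, 15)),
               "domain too short")
  # graft truncation longer than the physical graft
  g2 <- study_geometry(60)
  expect_error(build_outline(g2, domain_truncation(15, 15, 50)),
               "domain too short")
})
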