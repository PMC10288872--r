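## deterministic toy world used by several tests: a 10 x 4 section at x = 1.5
toy_section <- function() make_strip_section(10L, 4L, 1L)

test_that("streamline selection matches segment/voxel-box intersection", {
  sec <- toy_section()
  ## one through a mask voxel, one crossing outside the grid, one non-crossing
  s_in <- rbind(c(-3, 4.2, 1.7), c(6, 4.2, 1.7))
  s_out <- rbind(c(-3, 4.2, 30), c(6, 4.2, 30))
  s_non <- rbind(c(3, 1, 1), c(3.4, 8, 2))
  tract <- cc_tractogram(list(s_in, s_out, s_non))
  sel <- select_cc_streamlines(tract, sec)
  expect_identical(sel$indices, 1L)
  ## oracle: exhaustive segment-box intersection in the plane x = 1.5
  t <- (1.5 - s_in[1, 1]) / (s_in[2, 1] - s_in[1, 1])
  pt <- s_in[1, ] + t * (s_in[2, ] - s_in[1, ])
  hits <- which(abs(sec$coords[, 1] - pt[2]) <= 0.5 - 1e-12 &
                  abs(sec$coords[, 2] - pt[3]) <= 0.5 - 1e-12)
  expect_identical(sort(sel$crossing[[1]]), sort(hits))
  expect_length(hits, 1L)
})

test_that("streamlines entirely on one side are excluded", {
  sec <- toy_section()
  tract <- cc_tractogram(list(rbind(c(5, 4, 2), c(9, 5, 1))))
  sel <- select_cc_streamlines(tract, sec)
  expect_length(sel$indices, 0L)
})

test_that("multi-crossing streamlines are retained once with all voxels", {
  sec <- toy_section()
  zig <- rbind(c(-2, 2.1, 1.1), c(4, 2.1, 1.1), c(-2, 6.9, 2.9),
               c(4, 6.9, 2.9))
  sel <- select_cc_streamlines(cc_tractogram(list(zig)), sec)
  expect_identical(sel$indices, 1L)
  expect_gte(length(sel$crossing[[1]]), 2L)
  expect_identical(anyDuplicated(sel$crossing[[1]]), 0L)
})

test_that("endpoint_parcel maps points to parcels within the radius", {
  ## labelled voxels at x = 0 plane: labels along y
  arr <- array(0, c(6, 8, 4))
  arr[1, 2, 2] <- 4L   # voxel (0,1,1), centre (0,1,1)
  arr[1, 6, 2] <- 5L   # voxel (0,5,1)
  cortex <- cc_volume(arr)
  plane <- plane_spec(x = 2.5)
  ## inside a labelled voxel
  e <- endpoint_parcel(c(0.2, 1.3, 1.1), cortex, plane)
  expect_identical(e$label, 4L)
  expect_identical(e$side, "L")
  ## 1.2 mm away from the nearest labelled centre, radius 3
  e2 <- endpoint_parcel(c(1.2, 5, 1), cortex, plane, radius = 3)
  expect_identical(e2$label, 5L)
  ## oracle: exhaustive distance scan over labelled voxel centres
  sites <- rbind(c(0, 1, 1), c(0, 5, 1))
  d <- sqrt(colSums((t(sites) - c(1.2, 5, 1))^2))
  expect_identical(c(4L, 5L)[which.min(d)], e2$label)
  ## 5 mm from any labelled voxel -> none
  e3 <- endpoint_parcel(c(5, 5, 1), cortex, plane, radius = 3)
  expect_true(is.na(e3$label))
  expect_identical(e3$side, "R")
})

test_that("bundle assembly keeps homotopic pairs and tallies discards", {
  sec <- toy_section()
  arr <- array(0, c(4, 10, 4))
  arr[1, , ] <- 4L  # left cortex all precentral
  arr[4, 1:5, ] <- 4L; arr[4, 6:10, ] <- 5L  # right: precentral/postcentral
  cortex <- cc_volume(arr)
  plane <- sec$plane
  homo <- rbind(c(0, 2, 1), c(3, 2, 1))        # precentral L -> precentral R
  hetero <- rbind(c(0, 7, 2), c(3, 7, 2))      # precentral L -> postcentral R
  same <- rbind(c(2.6, 3, 1), c(3, 3, 1))      # both right of x = 1.5
  tract <- cc_tractogram(list(homo, hetero, same))
  sel <- select_cc_streamlines(tract, sec)
  b <- build_bundles(tract, sel, cortex, plane)
  expect_identical(b$bundles$precentral$members, 1L)
  expect_identical(b$qc$heterotopic, 1L)
  expect_identical(b$qc$kept, 1L)
  expect_identical(sum(vapply(b$bundles, function(x) length(x$members),
                              integer(1))), 1L)
})

test_that("phantom bundles recover the generator's ground truth", {
  ph <- tiny_phantom()
  sec <- extract_section(ph$wm_mask, ph$plane, 2L)
  sel <- select_cc_streamlines(ph$tractogram, sec)
  b <- build_bundles(ph$tractogram, sel, ph$cortex_vol, ph$plane)
  got <- vapply(b$bundles, function(x) length(x$members), integer(1))
  expect_identical(unname(got), unname(ph$ground_truth$bundle_counts))
  expect_identical(b$qc$heterotopic, ph$ground_truth$n_heterotopic)
  ## stray fibers never make it into the selection
  expect_identical(length(sel$indices),
                   sum(ph$ground_truth$bundle_counts) +
                     ph$ground_truth$n_heterotopic)
})

test_that("density accumulates weights once per voxel per streamline", {
  sec <- toy_section()
  mk_bundles <- function(crossings, weights) {
    b <- lapply(1:7, function(l) list(members = integer(0),
                                      weights = numeric(0),
                                      crossing = list()))
    names(b) <- names(cc_parcels())
    b[[1]] <- list(members = seq_along(crossings), weights = weights,
                   crossing = crossings)
    structure(list(bundles = b, qc = list()), class = "cc_bundles")
  }
  ## weight 2 through voxel 5, once
  d <- density_maps(mk_bundles(list(5L), 2), sec)
  expect_equal(unname(d[1, 5]), 2)
  expect_equal(sum(d), 2)
  ## a loop revisiting the same voxel contributes once
  d2 <- density_maps(mk_bundles(list(c(5L, 5L)), 2), sec)
  expect_equal(unname(d2[1, 5]), 2)
  ## brute-force accumulation oracle on random weighted streamlines
  set.seed(42)
  crossings <- replicate(9, sample(seq_len(nrow(sec$coords)),
                                   sample(1:3, 1)), simplify = FALSE)
  w <- runif(9, 0.2, 3)
  d3 <- density_maps(mk_bundles(crossings, w), sec)
  expected <- numeric(nrow(sec$coords))
  for (k in seq_along(crossings))
    for (v in unique(crossings[[k]])) expected[v] <- expected[v] + w[k]
  expect_equal(unname(d3[1, ]), expected)
})

test_that("regularized vote matches the printed kernel by hand", {
  sec <- make_strip_section(5L, 5L, 1L)
  imap_key <- paste(sec$coords[, 1], sec$coords[, 2])
  centre <- which(imap_key == "2 2")
  d <- matrix(0, 7, nrow(sec$coords))
  ## label B (=2) only at the centre; label A (=1) on all 8 neighbours
  d[2, centre] <- 1
  for (dy in -1:1) for (dz in -1:1) {
    if (dy == 0 && dz == 0) next
    d[1, which(imap_key == paste(2 + dy, 2 + dz))] <- 1
  }
  lm_ <- regularized_vote(d, sec)
  ## hand scores: A = 8/12 = 0.667 beats B = 1/2 -> isolated voxel removed
  expect_identical(lm_$labels[centre], 1L)
  ## single isolated density wins its own voxel when unopposed
  d0 <- matrix(0, 7, nrow(sec$coords)); d0[3, centre] <- 1
  expect_identical(regularized_vote(d0, sec)$labels[centre], 3L)
})

test_that("vote equals the brute-force kernel oracle on random instances", {
  sec <- make_strip_section(5L, 5L, 1L)
  set.seed(99)
  for (rep in 1:25) {
    nlab <- sample(2:7, 1)
    d <- matrix(0, 7, nrow(sec$coords))
    d[seq_len(nlab), ] <- round(matrix(rexp(nlab * nrow(sec$coords)),
                                       nlab), 3)
    d[d < 0.3] <- 0
    got <- regularized_vote(d, sec)$labels
    want <- oracle_vote(d, sec$coords)
    expect_identical(got, want)
  }
})

test_that("the vote errors out when every density map is zero", {
  sec <- toy_section()
  d <- matrix(0, 7, nrow(sec$coords))
  expect_error(regularized_vote(d, sec), "no callosal fibers")
})

test_that("label maps are invariant to global weight rescaling", {
  ph <- tiny_phantom()
  sec <- extract_section(ph$wm_mask, ph$plane, 2L)
  sel <- select_cc_streamlines(ph$tractogram, sec)
  b <- build_bundles(ph$tractogram, sel, ph$cortex_vol, ph$plane)
  d <- density_maps(b, sec)
  base <- fill_gaps(regularized_vote(d, sec), sec)
  for (c_ in c(0.02, 13.7)) {
    scaled <- fill_gaps(regularized_vote(d * c_, sec), sec)
    expect_identical(scaled$labels, base$labels)
  }
})

test_that("heterotopic fibers change nothing", {
  spec0 <- phantom_spec(ap_extent = 35L, height = 6L, seed = 7L,
                        heterotopic_fraction = 0)
  spec1 <- phantom_spec(ap_extent = 35L, height = 6L, seed = 7L,
                        heterotopic_fraction = 0.25)
  run <- function(spec) {
    ph <- generate_phantom(spec)
    res <- run_parcellation(ph$tractogram, ph$cortex_vol, ph$plane,
                            wm_mask = ph$wm_mask)
    res$labelmap$labels
  }
  expect_identical(run(spec0), run(spec1))
})

test_that("fill_gaps completes partial maps deterministically", {
  sec <- toy_section()
  n <- nrow(sec$coords)
  ## fully assigned map is unchanged
  full <- structure(list(labels = rep(3L, n), provenance = rep("voted", n)),
                    class = "cc_labelmap")
  expect_identical(fill_gaps(full, sec)$labels, full$labels)
  ## one interior unassigned voxel surrounded by label 5
  labels <- rep(5L, n)
  mid <- which(sec$coords[, 1] == 4 & sec$coords[, 2] == 2)
  labels[mid] <- NA
  part <- structure(list(labels = labels,
                         provenance = ifelse(is.na(labels), NA, "voted")),
                    class = "cc_labelmap")
  filled <- fill_gaps(part, sec)
  expect_identical(filled$labels[mid], 5L)
  expect_identical(filled$provenance[mid], "filled")
  ## strip with a 2-voxel gap between labels 4 and 6: nearest-label oracle
  labels2 <- rep(NA_integer_, n)
  labels2[sec$coords[, 1] <= 3] <- 4L
  labels2[sec$coords[, 1] >= 6] <- 6L
  part2 <- structure(list(labels = labels2,
                          provenance = ifelse(is.na(labels2), NA, "voted")),
                     class = "cc_labelmap")
  filled2 <- fill_gaps(part2, sec)
  expect_false(any(is.na(filled2$labels)))
  gap <- which(is.na(labels2))
  for (v in gap) {
    d4 <- min(sqrt(rowSums(sweep(sec$coords[labels2 %in% 4L, , drop = FALSE],
                                 2, sec$coords[v, ])^2)))
    d6 <- min(sqrt(rowSums(sweep(sec$coords[labels2 %in% 6L, , drop = FALSE],
                                 2, sec$coords[v, ])^2)))
    want <- if (d4 < d6) 4L else if (d6 < d4) 6L else 4L
    expect_identical(filled2$labels[v], want)
  }
})

test_that("parcel areas conserve the section area exactly", {
  sec <- toy_section()
  n <- nrow(sec$coords)
  labels <- rep(c(2L, 7L), length.out = n)
  labels[1:10] <- 1L
  lm_ <- structure(list(labels = labels, provenance = rep("voted", n)),
                   class = "cc_labelmap")
  ar <- parcel_areas(lm_, sec)
  expect_equal(ar$ccps[["frontopolar"]], 10 * sec$voxel_area)
  expect_identical(sum(ar$ccps), ar$cc_total)
  expect_equal(ar$cc_total, n * sec$voxel_area)
  expect_equal(unname(ar$ccps[3]), 0)  # absent label reports 0
})

test_that("cortical areas follow the per-vertex third-share rule", {
  ## unit right triangle, all vertices label 3: area 0.5 mm^2 = 0.005 cm^2
  m <- cc_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3)), c(3, 3, 3), c("L", "L", "L"))
  ca <- cortical_areas(m)
  expect_equal(ca$cxps[["posterior_prefrontal"]], 0.005)
  expect_equal(ca$tcxs, 0.005)
  ## two-triangle unit square, one triangle label 1, other label 2:
  ## shared vertices split each triangle's area across labels by thirds
  sq <- cc_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)),
                c(1, 1, 2, 2), rep("L", 4))
  ca2 <- cortical_areas(sq)
  ## oracle by hand: tri1 (labels 1,1,2) -> 1/3 mm^2 to 1, 1/6 to 2;
  ## tri2 (labels 1,2,2) -> 1/6 to 1, 1/3 to 2; each label gets 0.5 mm^2
  expect_equal(ca2$cxps[["frontopolar"]], 0.005)
  expect_equal(ca2$cxps[["anterior_prefrontal"]], 0.005)
  expect_equal(sum(ca2$cxps), ca2$tcxs)
})

test_that("cortical areas conserve TCxS on the phantom mesh", {
  ph <- tiny_phantom()
  ca <- cortical_areas(ph$cortex_mesh)
  expect_equal(sum(ca$cxps), ca$tcxs, tolerance = 1e-12)
  ## two flat ribbons of ap_extent x height mm^2 each
  expect_equal(ca$tcxs, 2 * 35 * 6 / 100)
})

test_that("geometric baseline bins follow the cut-point arithmetic", {
  sec <- make_strip_section(30L, 3L, 1L)
  lm_ <- witelson_baseline(sec, fractions = c(1 / 3, 1 / 2, 2 / 3, 4 / 5))
  widths <- tabulate(lm_$labels) / 3  # columns per bin
  expect_equal(widths / 30, c(1 / 3, 1 / 6, 1 / 6, 2 / 15, 1 / 5))
  ## anterior-most bin is label 1 and sits at the larger y coordinates
  ap <- section_ap(sec)
  expect_gt(min(ap[lm_$labels == 1]), max(ap[lm_$labels == 5]))

  sec10 <- make_strip_section(10L, 1L, 1L)
  lm10 <- witelson_baseline(sec10, fractions = 0.5)
  expect_equal(unname(tabulate(lm10$labels)), c(5L, 5L))
  lm_all <- witelson_baseline(sec10, fractions = numeric(0))
  expect_true(all(lm_all$labels == 1L))
  expect_error(witelson_baseline(sec10, fractions = c(0.5, 0.4)),
               "increasing")
  expect_error(witelson_baseline(sec10, fractions = c(0, 0.5)), "increasing")
})

test_that("qc_report flags fragmented parcels and absent labels", {
  sec <- make_strip_section(14L, 2L, 1L)
  n <- nrow(sec$coords)
  labels <- rep(2L, n)
  labels[sec$coords[, 1] %in% c(0, 13)] <- 1L  # label 1 in two pieces
  lm_ <- structure(list(labels = labels, provenance = rep("voted", n)),
                   class = "cc_labelmap")
  qc <- qc_report(lm_, sec, band = c(0.0, 1.0))
  expect_identical(qc$components[["frontopolar"]], 2L)
  expect_match(qc$warnings, "frontopolar", all = FALSE)
  expect_identical(qc$components[["occipital"]], 0L)
  expect_equal(qc$area_fraction[["occipital"]], 0)
})
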