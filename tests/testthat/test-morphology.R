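test_that("soma cylinder area is the lateral surface, end caps excluded", {
  s <- soma_cylinder(5, 10)
  expect_equal(pi * s$diam * s$length, 100 * pi)
  s1 <- soma_cylinder(1 / (2 * pi), 1)
  expect_equal(pi * s1$diam * s1$length, 1)
  expect_error(soma_cylinder(0, 10), class = "trnlab_invalid_argument")
  expect_error(soma_cylinder(5, -1), class = "trnlab_invalid_argument")
})

test_that("surface area is additive over sections and the generator is linear", {
  m <- synth_basal_tree(n_stems = 2, total_length = 600, branch_orders = 1,
                        rng_seed = 7)
  expect_equal(surface_area(m),
               sum(pi * m$diam * m$length))
  # one straight constant-diameter cable: area is exactly pi d L
  taper <- function(d) rep(1.5, length(d))
  m1 <- synth_basal_tree(n_stems = 1, total_length = 100, branch_orders = 0,
                         taper_profile = taper, rng_seed = 1)
  expect_equal(dendritic_area(m1), pi * 1.5 * 100)
  # doubling the diameter profile doubles the area
  m2 <- synth_basal_tree(n_stems = 3, total_length = 900, branch_orders = 2,
                         rng_seed = 5)
  taper2 <- function(d) 2 * (1.2 * exp(-d / 400) + 0.3)
  m2x <- synth_basal_tree(n_stems = 3, total_length = 900, branch_orders = 2,
                          taper_profile = taper2, rng_seed = 5)
  expect_equal(dendritic_area(m2x) / dendritic_area(m2), 2, tolerance = 1e-10)
})

test_that("synthetic trees are deterministic per seed and reject bad profiles", {
  a <- synth_basal_tree(rng_seed = 11)
  b <- synth_basal_tree(rng_seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- synth_basal_tree(rng_seed = 12)
  expect_false(identical(a$length, c$length))
  expect_error(synth_basal_tree(n_stems = 0), class = "trnlab_invalid_argument")
  expect_error(synth_basal_tree(taper_profile = function(d) d - 1e9),
               class = "trnlab_invalid_argument")
})

test_that("path distance sums section lengths from the soma origin", {
  secs <- dplyr::bind_rows(
    soma_cylinder(5, 10),
    tibble::tibble(id = 2L, parent_id = 1L, kind = "basal",
                   length = 100, diam = 1, n_comp = 1L),
    tibble::tibble(id = 3L, parent_id = 2L, kind = "basal",
                   length = 50, diam = 1, n_comp = 1L))
  m <- morphology(secs)
  expect_equal(path_distance(m, 1, 0.5), 0)  # soma is the origin
  expect_equal(path_distance(m, 2, 0.5), 50)
  expect_equal(path_distance(m, 3, 1), 150)
  expect_error(path_distance(m, 99), class = "trnlab_not_found")
  # monotone non-decreasing along the root-to-tip path
  d <- c(path_distance(m, 2, 0), path_distance(m, 2, 1),
         path_distance(m, 3, 0), path_distance(m, 3, 1))
  expect_true(all(diff(d) >= 0))
})

test_that("morphology validation rejects broken trees", {
  soma <- soma_cylinder(5, 10)
  expect_error(morphology(dplyr::bind_rows(soma, soma)),
               class = "trnlab_invalid_argument")  # duplicate ids
  two_roots <- dplyr::bind_rows(soma,
    tibble::tibble(id = 2L, parent_id = NA_integer_, kind = "soma",
                   length = 5, diam = 5, n_comp = 1L))
  expect_error(morphology(two_roots), class = "trnlab_invalid_argument")
  orphan <- dplyr::bind_rows(soma,
    tibble::tibble(id = 2L, parent_id = 77L, kind = "basal",
                   length = 5, diam = 1, n_comp = 1L))
  expect_error(morphology(orphan), class = "trnlab_invalid_argument")
})

test_that("area profile tracks the requested taper within 5% per bin", {
  taper <- function(d) 2 - d / 400
  m <- synth_basal_tree(n_stems = 4, total_length = 1600,
                        taper_profile = taper, branch_orders = 1, rng_seed = 3)
  prof <- area_profile(m, bin = 20)
  # expected area in a bin: sum over live branches of pi * taper(d) * 20
  comp <- purrr::map_dfr(which(m$kind == "basal"), function(i) {
    d0 <- path_distance(m, m$id[i], 0)
    tibble::tibble(d = d0 + seq(0.5, m$length[i] - 0.5, by = 1),
                   a = pi * m$diam[i])
  })
  comp$bin <- floor(comp$d / 20)
  exp_prof <- dplyr::summarise(dplyr::group_by(comp, bin),
                               area = sum(a), .groups = "drop")
  got <- prof$area[match((exp_prof$bin + 0.5) * 20, prof$distance)]
  rel <- abs(got - exp_prof$area) / exp_prof$area
  # the trailing bin is only partially covered by the tree; compare full bins
  expect_true(all(head(rel, -1) < 0.05))
})

test_that("SWC round-trip preserves geometry and a 3-point chain merges", {
  path <- withr::local_tempfile(fileext = ".swc")
  # hand-built 3-point straight chain, radius 1 (plus a soma root)
  writeLines(c("# test",
               "1 1 0 0 0 5 -1",
               "2 3 3 4 0 1 1",
               "3 3 6 8 0 1 2"), path)
  m <- read_swc(path)
  basal <- m[m$kind == "basal", ]
  expect_equal(nrow(basal), 1)          # constant-radius chain merged
  expect_equal(basal$length, 10)        # two 5-um euclidean segments
  expect_equal(basal$diam, 2)

  # round trip of a tapering synthetic tree
  tree <- synth_basal_tree(n_stems = 3, total_length = 700, branch_orders = 2,
                           rng_seed = 21)
  out <- withr::local_tempfile(fileext = ".swc")
  write_swc(tree, out)
  back <- read_swc(out)
  expect_equal(nrow(back), nrow(tree))
  expect_equal(surface_area(back), surface_area(tree), tolerance = 1e-9)
  expect_equal(sort(back$length), sort(tree$length), tolerance = 1e-6)
  expect_equal(sort(back$diam), sort(tree$diam), tolerance = 1e-6)
  # tip path distances identical (topology preserved)
  tips <- function(mm) {
    is_tip <- !(mm$id %in% mm$parent_id)
    sort(vapply(mm$id[is_tip & mm$kind == "basal"],
                function(id) path_distance(mm, id, 1), numeric(1)))
  }
  expect_equal(tips(back), tips(tree), tolerance = 1e-6)
})

test_that("malformed SWC files are rejected", {
  p <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 0 0 5 5 -1"), p)  # two roots
  expect_error(read_swc(p), class = "trnlab_format_error")
  writeLines(c("1 3 0 0 0 1 2", "2 3 0 0 5 1 1"), p)    # cycle, no root
  expect_error(read_swc(p), class = "trnlab_format_error")
  writeLines("1 1 0 0 0 5", p)                           # 6 columns
  expect_error(read_swc(p), class = "trnlab_format_error")
})
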