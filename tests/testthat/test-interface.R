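test_that("interface membership follows the heavy-atom cutoff definition", {
  m <- two_residue_model(gap = 4.0)
  hit <- interface_residues(m, cutoff = 5.0)
  expect_equal(interface_keys(hit), c("A|1", "B|2"))
  expect_equal(nrow(interface_residues(m, cutoff = 3.0)), 0)
  # boundary is strict
  expect_equal(nrow(interface_residues(m, cutoff = 4.0)), 0)

  single <- as_complex_model(tibble::tibble(
    name = "CA", element = "C", resno = 1, resname = "GLY", chain = "A",
    x = 0, y = 0, z = 0
  ))
  expect_error(interface_residues(single), class = "mdcontact_chain_error")
})

test_that("interface residues match the all-pairs oracle on random complexes", {
  withr::local_seed(21)
  for (k in 1:30) {
    m <- generate_complex(10, separation = runif(1, 2, 7),
                          seed = sample.int(1e6, 1))
    m <- transform_coords(m, random_rotation(), rnorm(3, sd = 10))
    cutoff <- runif(1, 3, 8)
    expect_equal(interface_keys(interface_residues(m, cutoff)),
                 oracle_interface_residues(m, cutoff))
  }
})

hbond_pair_model <- function(no_dist, with_h_angle = NULL) {
  atoms <- tibble::tibble(
    name = c("N", "CA", "O", "C"),
    element = c("N", "C", "O", "C"),
    resno = c(1, 1, 101, 101),
    resname = "GLY",
    chain = c("A", "A", "B", "B"),
    x = c(0, -1.4, no_dist, no_dist + 1.2),
    y = 0, z = 0
  )
  if (!is.null(with_h_angle)) {
    # hydrogen on the donor N, 1.0 A away, at the requested D-H...A angle
    theta <- (180 - with_h_angle) * pi / 180
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      name = "H", element = "H", resno = 1, resname = "GLY", chain = "A",
      x = cos(theta), y = sin(theta), z = 0
    ))
  }
  as_complex_model(atoms, model_id = "hb")
}

test_that("hydrogen-bond detection applies distance, covalent and angle gates", {
  bonds <- detect_interface_hbonds(hbond_pair_model(2.9))
  expect_equal(nrow(bonds), 1)
  expect_equal(bonds$distance, 2.9, tolerance = 1e-12)
  expect_equal(bonds$donor_chain, "A")
  expect_equal(bonds$acceptor_chain, "B")

  # same heavy-atom geometry, explicit H at 95 degrees: angle gate rejects
  expect_equal(nrow(detect_interface_hbonds(hbond_pair_model(2.9, 95))), 0)
  # near-linear H passes
  expect_equal(nrow(detect_interface_hbonds(hbond_pair_model(2.9, 175))), 1)
  # far apart and covalent-range pairs are not bonds
  expect_equal(nrow(detect_interface_hbonds(hbond_pair_model(50))), 0)
  expect_equal(nrow(detect_interface_hbonds(hbond_pair_model(1.5))), 0)
})

test_that("hydrogen-bond detection matches exhaustive enumeration and is symmetric", {
  withr::local_seed(31)
  for (k in 1:20) {
    spec <- ensemble_spec(c(m = sample(0:5, 1)), seed = sample.int(1e6, 1))
    m <- generate_ensemble(spec)[[1]]
    expect_equal(count_interface_hbonds(m), oracle_hbond_count(m))
    # chain relabelling leaves the unordered bond set unchanged
    swapped <- m
    swapped$chain <- ifelse(m$chain == "A", "B", "A")
    b1 <- detect_interface_hbonds(m)
    b2 <- detect_interface_hbonds(swapped)
    expect_equal(
      sort(paste(pmin(b1$donor_serial, b1$acceptor_serial),
                 pmax(b1$donor_serial, b1$acceptor_serial))),
      sort(paste(pmin(b2$donor_serial, b2$acceptor_serial),
                 pmax(b2$donor_serial, b2$acceptor_serial)))
    )
  }
})

test_that("hydrogen-bond counts are invariant under rigid-body motion", {
  withr::local_seed(41)
  m <- generate_ensemble(c(m = 4), seed = 11, hydrogens = TRUE)[[1]]
  n0 <- count_interface_hbonds(m)
  for (k in 1:5) {
    mt <- transform_coords(m, random_rotation(), rnorm(3, sd = 25))
    expect_equal(count_interface_hbonds(mt), n0)
  }
})

test_that("model ranking is descending with stable ties and top-n truncation", {
  counts <- tibble::tibble(
    model_id = c("560", "3413", "105", "819", "994", "2079", "3521",
                 "1015", "1742", "708", "x1", "x2"),
    hbond_count = c(9, 9, 9, 8, 8, 8, 8, 8, 8, 8, 7, 6)
  )
  r <- rank_models(counts, top_n = 10)
  expect_equal(nrow(r), 10)
  expect_equal(r$rank, 1:10)
  expect_equal(r$model_id[1], "560")
  expect_equal(r$hbond_count[1], 9)
  # ties keep input order
  expect_equal(r$model_id, counts$model_id[1:10])
  expect_true(all(diff(r$hbond_count) <= 0))

  expect_equal(rank_models(counts[3, ])$rank, 1)
  expect_error(rank_models(counts[0, ]), class = "mdcontact_empty_input")
})

test_that("ranking a shuffled planted ensemble agrees with a sort oracle", {
  withr::local_seed(11)
  planted <- sample(0:6, 12, replace = TRUE)
  names(planted) <- paste0("m", seq_along(planted))
  models <- generate_ensemble(planted, seed = 11)
  r <- rank_models(models, top_n = length(models))
  # oracle: exhaustive stable selection sort on the planted counts
  ids <- names(planted)
  cnt <- planted
  expected <- character(0)
  while (length(ids) > 0) {
    i <- which(cnt == max(cnt))[1]
    expected <- c(expected, ids[i])
    ids <- ids[-i]
    cnt <- cnt[-i]
  }
  expect_equal(r$model_id, expected)
  expect_equal(r$hbond_count, unname(planted[expected]))
})
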