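make_model <- function(atoms) as_complex_model(atoms, model_id = "fix")

test_that("residue center of mass is the mass-weighted mean", {
  one <- make_model(tibble::tibble(
    name = "CA", element = "C", resno = 1, resname = "GLY", chain = "A",
    x = 1, y = 2, z = 3
  ))
  expect_equal(residue_center_of_mass(one), c(1, 2, 3))

  two <- make_model(tibble::tibble(
    name = c("C1", "C2"), element = "C", resno = 1, resname = "GLY",
    chain = "A", x = c(0, 2), y = 0, z = 0
  ))
  expect_equal(residue_center_of_mass(two), c(1, 0, 0))

  withr::local_seed(5)
  gly <- make_model(tibble::tibble(
    name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    resno = 1, resname = "GLY", chain = "A",
    x = rnorm(4), y = rnorm(4), z = rnorm(4)
  ))
  expect_equal(residue_center_of_mass(gly), oracle_com(gly))
})

test_that("per-frame minimum COM distance matches the exhaustive partner scan", {
  # one partner residue: distance is simply to its COM
  m <- make_model(tibble::tibble(
    name = c("C1", "C2", "C1", "C2"), element = "C",
    resno = c(1, 1, 50, 50), resname = "GLY",
    chain = c("A", "A", "B", "B"),
    x = c(0, 2, 6, 8), y = 0, z = 0
  ))
  got <- per_frame_min_com_distance(m, 1, "A", "B")
  expect_equal(got$distance, 6)
  expect_equal(got$partner_resno, 50)

  withr::local_seed(17)
  for (k in 1:20) {
    mm <- generate_complex(10, separation = runif(1, 2, 6),
                           seed = sample.int(1e6, 1))
    res <- sample(1:10, 1)
    got <- per_frame_min_com_distance(mm, res, "A", "B")
    want <- oracle_min_com_distance(mm, res, "A", "B")
    expect_equal(got$distance, want$distance)
    expect_equal(got$partner_resno, want$partner_resno)
  }

  expect_error(per_frame_min_com_distance(m, 99, "A", "B"),
               class = "mdcontact_lookup_error")
})

test_that("COM distance ties resolve to the lowest partner residue number", {
  m <- make_model(tibble::tibble(
    name = "CA", element = "C",
    resno = c(1, 70, 60), resname = "GLY",
    chain = c("A", "B", "B"),
    x = c(0, 5, -5), y = 0, z = 0
  ))
  expect_equal(per_frame_min_com_distance(m, 1, "A", "B")$partner_resno, 60)
})

test_that("atomic contact uses a strict heavy-atom cutoff", {
  expect_true(atomic_contact(two_residue_model(4.4), 1, "A", "B", cutoff = 4.5))
  expect_false(atomic_contact(two_residue_model(4.5), 1, "A", "B", cutoff = 4.5))
  withr::local_seed(19)
  for (k in 1:20) {
    mm <- generate_complex(8, separation = runif(1, 3, 6),
                           seed = sample.int(1e6, 1))
    res <- sample(1:8, 1)
    cutoff <- runif(1, 3.5, 6)
    expect_equal(atomic_contact(mm, res, "A", "B", cutoff),
                 oracle_atomic_contact(mm, res, "A", "B", cutoff))
  }
})

test_that("degenerate planted trajectories give exact persistence and distance stats", {
  tr <- generate_trajectory(trajectory_spec(
    10, tibble::tibble(resno = 1, p = 1, mu = 3, sigma = 0),
    frame_jitter = 0, seed = 4
  ))
  an <- analyze_replicate(tr, "A", "B")
  row <- an$summary[an$summary$resno == 1, ]
  expect_equal(row$persistence_fraction, 1)
  expect_equal(row$mean_distance, 3, tolerance = 0.05 / 3)
  expect_lt(row$sd_distance, 0.05)
  expect_true(row$passes_criteria)

  tr0 <- generate_trajectory(trajectory_spec(
    10, tibble::tibble(resno = 1, p = 0, mu = 3, sigma = 0), seed = 4
  ))
  row0 <- tidy(analyze_replicate(tr0, "A", "B"))
  expect_equal(row0$persistence_fraction[row0$resno == 1], 0)
  expect_false(row0$passes_criteria[row0$resno == 1])
})

test_that("planted contact probability and distance moments are recovered", {
  n <- 200
  tr <- generate_trajectory(trajectory_spec(
    n, tibble::tibble(resno = 256, p = 0.90, mu = 4.44, sigma = 0.21),
    background_residues = 1, seed = 42
  ))
  row <- tidy(analyze_replicate(tr, "A", "B"))
  row <- row[row$resno == 256, ]
  iv <- recovery_intervals(0.90, 4.44, 0.21, n)
  expect_true(in_interval(row$persistence_fraction, iv$p))
  expect_true(in_interval(row$mean_distance, 4.44 + c(-3, 3) * 0.21 / sqrt(n)))
  expect_true(row$sd_distance >= 0.15 && row$sd_distance <= 0.29)
})

test_that("duplicating every frame leaves persistence, mean and sd unchanged", {
  tr <- generate_trajectory(trajectory_spec(
    30, tibble::tibble(resno = 1, p = 0.7, mu = 5, sigma = 0.5), seed = 13
  ))
  dup <- tr
  shifted <- dplyr::mutate(tibble::as_tibble(tr), frame = frame + n_frames(tr))
  dup <- mdcontact:::new_trajectory(
    dplyr::bind_rows(tibble::as_tibble(tr), shifted), replicate_id = "dup"
  )
  s1 <- tidy(analyze_replicate(tr, "A", "B"))
  s2 <- tidy(analyze_replicate(dup, "A", "B"))
  expect_equal(s2$persistence_fraction, s1$persistence_fraction)
  expect_equal(s2$mean_distance, s1$mean_distance)
  expect_equal(s2$sd_distance, s1$sd_distance)
})

test_that("sd is zero iff the distance series is constant, and mean bounds hold", {
  tr <- generate_trajectory(trajectory_spec(
    40, tibble::tibble(resno = c(1, 2), p = c(0.8, 1),
                       mu = c(5, 4), sigma = c(0.4, 0)),
    frame_jitter = 0, seed = 23
  ))
  an <- analyze_replicate(tr, "A", "B")
  ser <- an$series
  for (r in unique(ser$resno)) {
    v <- ser$distance[ser$resno == r]
    row <- an$summary[an$summary$resno == r, ]
    expect_gte(row$mean_distance, min(v))
    expect_equal(row$sd_distance == 0, max(v) - min(v) == 0)
  }
})

test_that("conjunctive criteria select a subset of persistence-only selection", {
  lig <- tibble::tibble(resno = 1:4, p = c(0.95, 0.9, 0.85, 0.2),
                        mu = c(4.4, 6.5, 4.8, 4.0), sigma = 0.3)
  tr <- generate_trajectory(trajectory_spec(80, lig, seed = 29))
  only <- analyze_replicate(tr, "A", "B",
                            criteria = contact_criteria(criteria_mode = "persistence_only"))
  both <- analyze_replicate(tr, "A", "B",
                            criteria = contact_criteria(criteria_mode = "persistence_and_com"))
  expect_true(all(selected_residues(both) %in% selected_residues(only)))
  # the COM gate actually bites for a persistent-but-distant residue
  expect_true("GLY2" %in% selected_residues(only))
  expect_false("GLY2" %in% selected_residues(both))
})

test_that("aggregation pools frames across replicates with population sd", {
  mk_const <- function(dist, id, seed) {
    generate_trajectory(trajectory_spec(
      10, tibble::tibble(resno = 1, p = 1, mu = dist, sigma = 0),
      frame_jitter = 0, seed = seed, replicate_id = id
    ))
  }
  a4 <- analyze_replicate(mk_const(4, "r1", 1), "A", "B")
  a6 <- analyze_replicate(mk_const(6, "r2", 2), "A", "B")
  agg <- aggregate_replicates(list(a4, a6))
  expect_equal(agg$mean_distance, 5, tolerance = 1e-3)
  expect_equal(agg$sd_distance, 1, tolerance = 1e-2)
  expect_equal(agg$n_frames, 20)
  expect_equal(agg$n_pass, 2)

  # single replicate: aggregate equals that replicate's summary
  single <- aggregate_replicates(list(a4))
  expect_equal(single$mean_distance, a4$summary$mean_distance)
  expect_equal(single$sd_distance, a4$summary$sd_distance)

  # replicate-means variant
  rm_agg <- aggregate_replicates(list(a4, a6), method = "replicate_means")
  expect_equal(rm_agg$mean_distance, 5, tolerance = 1e-3)

  expect_error(aggregate_replicates(list()), class = "mdcontact_empty_input")
})

test_that("contact statistics are invariant under rigid-body transforms", {
  tr <- generate_trajectory(trajectory_spec(
    25, tibble::tibble(resno = 1:2, p = c(0.9, 0.4), mu = c(4.5, 7), sigma = 0.3),
    seed = 37
  ))
  withr::local_seed(8)
  trt <- transform_coords(tr, random_rotation(), rnorm(3, sd = 30))
  s1 <- tidy(analyze_replicate(tr, "A", "B"))
  s2 <- tidy(analyze_replicate(trt, "A", "B"))
  expect_equal(s2$persistence_fraction, s1$persistence_fraction)
  expect_equal(s2$mean_distance, s1$mean_distance)
  expect_equal(s2$sd_distance, s1$sd_distance)
})

test_that("distance table ranking puts the closest residue first", {
  d <- tibble::tibble(residue = c("B2", "A1", "C3"),
                      mean_distance = c(6.1, 4.4, 5.2))
  r <- rank_by_distance(d)
  expect_equal(r$residue, c("A1", "C3", "B2"))
  expect_equal(r$rank, 1:3)
})
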