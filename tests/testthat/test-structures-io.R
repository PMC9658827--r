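pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     alt = " ", occ = 1.0, element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0, element)
}

test_that("read_pdb parses a minimal two-chain structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " N  ", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, " O  ", "SER", "B", 5, 2.9, 0, 0),
    "END"
  ), f)
  m <- read_pdb(f)
  expect_s3_class(m, "complex_model")
  expect_equal(chain_ids(m), c("A", "B"))
  expect_equal(nrow(m), 2)
  expect_equal(m$element, c("N", "O"))
  expect_equal(m$mass, c(14.007, 15.999))
})

test_that("altloc duplicates keep the highest occupancy, ties the first", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " CA ", "GLY", "A", 1, 1.0, 0, 0, alt = "A", occ = 0.6),
    pdb_line(2, " CA ", "GLY", "A", 1, 2.0, 0, 0, alt = "B", occ = 0.4),
    pdb_line(3, " CA ", "GLY", "B", 2, 9.0, 0, 0, alt = "A", occ = 0.5),
    pdb_line(4, " CA ", "GLY", "B", 2, 8.0, 0, 0, alt = "B", occ = 0.5),
    "END"
  ), f)
  m <- read_pdb(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$x, c(1.0, 9.0))
})

test_that("waters and HETATM records are excluded by default", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " CA ", "GLY", "A", 1, 0, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_line(2, " O  ", "HOH", "A", 90, 5, 0, 0)),
    sub("^ATOM  ", "HETATM", pdb_line(3, "FE  ", "HEM", "A", 91, 9, 0, 0, element = "FE")),
    "END"
  ), f)
  expect_equal(nrow(read_pdb(f)), 1)
})

test_that("read_pdb error cases: missing file, empty structure, unknown element", {
  expect_error(read_pdb(tempfile()), class = "mdcontact_io_error")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing", "END"), f)
  expect_error(read_pdb(f), class = "mdcontact_empty_structure")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " QQ ", "GLY", "A", 1, 0, 0, 0, element = "XX"),
    "END"
  ), f2)
  expect_error(read_pdb(f2), "serial 1", class = "mdcontact_element_error")
})

test_that("generated complexes round-trip through PDB at 3 decimals", {
  m <- generate_complex(10, separation = 4.5, seed = 9)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  expect_equal(
    paste(m$chain, m$resno, m$resname, m$name, sep = "|"),
    paste(m2$chain, m2$resno, m2$resname, m2$name, sep = "|")
  )
  expect_true(max(abs(m2$x - round(m$x, 3)),
                  abs(m2$y - round(m$y, 3)),
                  abs(m2$z - round(m$z, 3))) < 1e-9)
})

test_that("trajectories read back with identical frames and topology", {
  spec <- trajectory_spec(
    20, tibble::tibble(resno = 10, p = 0.8, mu = 5, sigma = 0.3),
    background_residues = 1, seed = 7
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  traj <- generate_trajectory(spec, path = f)
  t1 <- read_trajectory(f)
  t2 <- read_trajectory(f)
  expect_identical(t1, t2)
  expect_equal(n_frames(t1), 20)
  expect_identical(topology_key(t1), topology_key(traj))
  expect_equal(t1$x, traj$x, tolerance = 1e-3)

  # single frame file
  m <- generate_complex(3, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f1)
  expect_equal(n_frames(read_trajectory(f1)), 1)
})

test_that("a frame with a dropped atom raises a topology error naming it", {
  spec <- trajectory_spec(
    5, tibble::tibble(resno = 1, p = 1, mu = 4, sigma = 0),
    seed = 3
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  generate_trajectory(spec, path = f)
  lines <- readLines(f)
  starts <- grep("^MODEL", lines)
  drop <- grep("^ATOM", lines)
  drop <- drop[drop > starts[3]][1]
  writeLines(lines[-drop], f)
  expect_error(read_trajectory(f), "frame 3",
               class = "mdcontact_topology_error")
})

test_that("write_table renders headers and 2-decimal distances", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(tibble::tibble(residue = character(), mean_distance = double()), f)
  expect_equal(readLines(f), "residue\tmean_distance")

  rows <- tibble::tibble(
    residue = c("GLY256", "THR272"),
    mean_distance = c(4.4411, 5.5349),
    sd_distance = c(0.208, 0.614)
  )
  write_table(rows, f)
  txt <- readLines(f)
  expect_equal(txt[1], "residue\tmean_distance\tsd_distance")
  expect_equal(txt[2], "GLY256\t4.44\t0.21")

  back <- read_table_tsv(f)
  expect_equal(back$mean_distance, round(rows$mean_distance, 2))
  expect_equal(back$sd_distance, round(rows$sd_distance, 2))
})
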