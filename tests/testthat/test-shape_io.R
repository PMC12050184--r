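# Point-cloud, landmark and model archive I/O.

test_that("XYZ files parse in order and round-trip bit-for-bit", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0", "0 1 0", "0 0 1"), path)
  cl <- read_point_cloud(path)
  expect_equal(nrow(cl$points), 4)
  expect_identical(cl$points,
                   matrix(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1), 4, 3))

  set.seed(11)
  cl2 <- point_cloud(matrix(rnorm(30, sd = pi), 10, 3))
  out <- withr::local_tempfile(fileext = ".xyz")
  write_point_cloud(cl2, out)
  back <- read_point_cloud(out)
  expect_identical(back$points, cl2$points)  # full-precision identity
})

test_that("malformed or too-small point files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 banana 0", "0 1 0", "1 1 1"), path)
  expect_error(read_point_cloud(path), "line 2")
  writeLines(c("0 0 0", "1 0 0", "0 1 0"), path)
  expect_error(read_point_cloud(path), "at least 4")
})

test_that("ASCII STL yields unique vertices in file order", {
  # unit cube as 12 triangles; oracle = distinct coordinate triples
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tri <- rbind(
    c(1, 2, 3), c(2, 4, 3), c(5, 7, 6), c(6, 7, 8),
    c(1, 3, 5), c(3, 7, 5), c(2, 6, 4), c(4, 6, 8),
    c(1, 5, 2), c(2, 5, 6), c(3, 4, 7), c(4, 8, 7))
  lines <- c("solid cube")
  for (f in seq_len(nrow(tri))) {
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               apply(v[tri[f, ], ], 1, function(p)
                 paste("vertex", paste(p, collapse = " "))),
               "endloop", "endfacet")
  }
  lines <- c(lines, "endsolid cube")
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(lines, path)
  cl <- read_point_cloud(path)
  expect_equal(nrow(cl$points), 8)
  # file order of first occurrence, exactly the distinct triples
  expect_equal(cl$points[1:3, ], unname(v[tri[1, ], ]),
               ignore_attr = TRUE)
  expect_identical(nrow(unique(cl$points)), 8L)
})

test_that("PLY round-trips with and without normals; OBJ v records parse", {
  set.seed(3)
  P <- matrix(rnorm(18), 6, 3)
  N <- t(apply(matrix(rnorm(18), 6, 3), 1, function(v) v / sqrt(sum(v^2))))
  path <- withr::local_tempfile(fileext = ".ply")

  write_point_cloud(point_cloud(P, N), path)
  expect_true(any(grepl("property double nx", readLines(path))))
  back <- read_point_cloud(path)
  expect_identical(back$points, P)
  expect_identical(back$normals, N)

  write_point_cloud(point_cloud(P), path)
  expect_false(any(grepl("nx", readLines(path))))
  expect_null(read_point_cloud(path)$normals)

  obj <- withr::local_tempfile(fileext = ".obj")
  write_point_cloud(point_cloud(P), obj)
  expect_identical(read_point_cloud(obj)$points, P)
})

test_that("binary little-endian PLY vertices are read", {
  P <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2.25, 0, 0, 0, -3.5), 4, 3,
              byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 4", "property float x", "property float y",
               "property float z", "end_header"), con)
  writeBin(as.numeric(t(P)), con, size = 4, endian = "little")
  close(con)
  expect_equal(read_point_cloud(path)$points, P, tolerance = 1e-7)
})

test_that("landmark files map names case-insensitively and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z", "a,0,0,0", "B,3,4,0", "c,10,0,0", "D,9,1,2"),
             path)
  lm <- read_landmarks(path)
  expect_equal(lm$A, c(0, 0, 0))
  expect_equal(lm$B, c(3, 4, 0))
  expect_equal(lm$D, c(9, 1, 2))

  writeLines(c("name,x,y,z", "A,0,0,0", "B,3,4,0", "C,10,0,0"), path)
  expect_error(read_landmarks(path), "D")

  writeLines(c("name,x,y,z", "A,0,0,0", "A,1,1,1", "B,3,4,0", "C,10,0,0",
               "D,9,1,2"), path)
  expect_error(read_landmarks(path), "duplicate.*A")

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"A":[0,0,0],"b":[3,4,0],"C":[10,0,0],"D":[9,1,2]}', js)
  expect_equal(read_landmarks(js)$B, c(3, 4, 0))
})

test_that("model archives round-trip, and reject truncation and wrong types", {
  set.seed(5)
  m <- fit_ssm(matrix(rnorm(60), 6, 10), alpha = 0.9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path, seed = 5, config = list(alpha = 0.9))
  back <- load_model(path, expected_type = "shape_model")
  expect_identical(back$eigenvalues, m$eigenvalues)
  expect_identical(back$eigenvectors, m$eigenvectors)

  # truncated archive -> integrity error
  raw <- readBin(path, "raw", file.size(path))
  trunc <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[seq_len(20)], trunc)
  expect_error(load_model(trunc), "integrity")

  # wrong-type load names expected and actual
  clf <- init_classifier(3, hidden_size = 4, seed = 1)
  save_model(clf, path)
  expect_error(load_model(path, expected_type = "shape_model"),
               "expected shape_model, actual nn_classifier")
})

test_that("manifests validate labels and path uniqueness", {
  dir <- withr::local_tempdir()
  writeLines(c("cloud,landmarks,group", "a.ply,,normal", "b.ply,b.csv,colles"),
             file.path(dir, "m.csv"))
  m <- read_manifest(file.path(dir, "m.csv"))
  expect_equal(nrow(m), 2)
  expect_true(is.na(m$landmarks[1]))
  expect_equal(as.character(m$group), c("normal", "colles"))

  writeLines(c("cloud,landmarks,group", "a.ply,,normal", "a.ply,,smith"),
             file.path(dir, "m.csv"))
  expect_error(read_manifest(file.path(dir, "m.csv")), "duplicate")
  writeLines(c("cloud,landmarks,group", "a.ply,,greenstick"),
             file.path(dir, "m.csv"))
  expect_error(read_manifest(file.path(dir, "m.csv")), "greenstick")
})
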