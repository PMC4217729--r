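test_that("GAL files round-trip and neighbor counts are preserved", {
  p <- write_gal(c("2", "A 1", "B", "B 1", "A"))
  adj <- read_neighbor_list(p)
  expect_s3_class(adj, "adjacency")
  expect_identical(adj$unit_ids, c("A", "B"))
  expect_identical(adj$n_neighbors, c(1L, 1L))

  p3 <- write_gal(c("3", "A 1", "B", "B 2", "A C", "C 1", "B"))
  adj3 <- read_neighbor_list(p3)
  expect_identical(adj3$n_neighbors, c(1L, 2L, 1L))

  out <- tempfile(fileext = ".gal")
  write_neighbor_list(adj3, out)
  back <- read_neighbor_list(out)
  expect_identical(back$unit_ids, adj3$unit_ids)
  expect_identical(back$neighbors, adj3$neighbors)
})

test_that("JSON dialect reads the same graph as GAL", {
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = list("B"), B = list("A", "C"), C = list("B")),
                       p)
  adj <- read_neighbor_list(p)
  expect_identical(adj$n_neighbors, c(1L, 2L, 1L))
  expect_identical(adj$neighbors[[2]], c(1L, 3L))
})

test_that("asymmetric and malformed neighbor files are rejected with context", {
  p <- write_gal(c("2", "A 1", "B", "B 0"))
  expect_error(read_neighbor_list(p), "A.*B|\\(A,B\\)")
  p2 <- write_gal(c("2", "A onlyonefieldmissing", "B", "B 0"))
  expect_error(read_neighbor_list(p2), "line")
  expect_error(read_neighbor_list(write_gal("notanumber")), "line 1")
  expect_error(adjacency(c("A", "B"), list(c(1L, 2L), 1L)), "itself")
  expect_error(adjacency(c("A", "A"), list(2L, 1L)), "unique")
})

test_that("lattice adjacency matches rook-contiguity structure", {
  a12 <- build_lattice_adjacency(1, 2)
  expect_identical(a12$n_neighbors, c(1L, 1L))
  expect_identical(a12$neighbors, list(2L, 1L))

  a22 <- build_lattice_adjacency(2, 2)
  expect_true(all(a22$n_neighbors == 2L))

  a13 <- build_lattice_adjacency(13, 13)
  expect_length(a13$unit_ids, 169)
  expect_identical(sum(a13$n_neighbors), 2L * 312L)  # 2 * (13*12 + 13*12)
  interior <- as.vector(outer(2:12, 2:12,
                              function(r, c) (r - 1) * 13 + c))
  expect_true(all(a13$n_neighbors[interior] == 4L))

  expect_error(build_lattice_adjacency(1, 1), "at least 2")
})

test_that("lattice edge-count identity holds across sizes", {
  for (rc in list(c(2, 3), c(3, 3), c(4, 7), c(1, 9))) {
    a <- build_lattice_adjacency(rc[1], rc[2])
    expect_equal(sum(a$n_neighbors),
                 2 * (rc[1] * (rc[2] - 1) + rc[2] * (rc[1] - 1)))
    # symmetry and irreflexivity hold exactly for accepted structures
    for (i in seq_along(a$unit_ids)) {
      expect_false(i %in% a$neighbors[[i]])
      for (j in a$neighbors[[i]]) expect_true(i %in% a$neighbors[[j]])
    }
  }
})

test_that("validation reports islands and connected components", {
  r <- validate_adjacency(build_lattice_adjacency(2, 2))
  expect_identical(r$n_islands, 0L)
  expect_identical(r$n_components, 1L)

  iso <- adjacency(c("x", "y", "z"), list(integer(0), integer(0), integer(0)))
  r2 <- validate_adjacency(iso)
  expect_identical(r2$n_islands, 3L)
  expect_identical(r2$n_components, 3L)

  pairs <- adjacency(c("a", "b", "c", "d"), list(2L, 1L, 4L, 3L))
  r3 <- validate_adjacency(pairs)
  expect_identical(r3$n_islands, 0L)
  expect_identical(r3$n_components, 2L)
  expect_identical(r3$component, c(1L, 1L, 2L, 2L))
})

test_that("centroid tables are validated", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(unit_id = c("a", "b"), name = c("A", "B"),
                       lon = c(3, 3.1), lat = c(50, 50.1)),
            p, row.names = FALSE)
  cent <- read_centroids(p)
  expect_identical(cent$unit_id, c("a", "b"))
  write.csv(data.frame(unit_id = "a", name = "A", lon = NA, lat = 1),
            p, row.names = FALSE)
  expect_error(read_centroids(p), "finite")
})
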