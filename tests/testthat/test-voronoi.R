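# Expected values in the first block were computed independently with
# scipy.spatial.Voronoi (cell areas by the shoelace formula on the region
# polygons; first-rank densities from ridge adjacency with zero-length
# ridges dropped) on the identical 30-point fixture, and frozen here.
test_that("cell areas and first-rank densities match the scipy oracle", {
  withr::with_seed(321, {
    pts <- cbind(round(runif(30) * 1000, 3), round(runif(30) * 1000, 3))
  })
  dm <- voronoi_densities(pts)
  interior <- c(1, 3, 5, 6, 7, 9, 10, 11, 12, 13, 15, 16, 17, 18, 19, 20,
                21, 24, 25, 26, 28, 30)
  expect_equal(which(!dm$hull), interior)
  oracle_area <- c(28734.739450, 74319.172963, 22247.239190, 45847.841479,
                   17561.465468, 13105.205461, 34832.995967, 31312.283514,
                   13665.087574, 42969.735619, 868853.850616, 27749.725357,
                   47054.847755, 112233.723827, 29130.440662, 42193.967460,
                   40535.457175, 96688.196102, 11868.081561, 34475.442146,
                   34007.686148, 12780.921263)
  expect_equal(dm$area[interior], oracle_area, tolerance = 1e-8)
  oracle_delta <- c(2.633925393e-05, 1.770552646e-05, 2.102941449e-05,
                    2.946838134e-05, 7.33970023e-06, 3.969165135e-05,
                    2.61756754e-05, 5.181433259e-06, 3.324450817e-05,
                    2.641772077e-05, 3.883640977e-06, 2.621750584e-05,
                    1.613449619e-05, 4.565311775e-06, 2.484581484e-05,
                    2.107261858e-05, 3.198798948e-05, 2.007426368e-05,
                    5.216422542e-05, 3.248079896e-05, 2.317353815e-05,
                    4.039488664e-05)
  expect_equal(dm$delta_i[interior], oracle_delta, tolerance = 1e-8)
  expect_equal(dm$delta, 2.40721979964e-05, tolerance = 1e-9)
})

test_that("square lattice: interior density 1/a^2 with 4 neighbours", {
  a <- 100
  g <- as.matrix(expand.grid(x = a * (0:14), y = a * (0:14)))
  dm <- voronoi_densities(g)
  deep <- g[, 1] >= 2 * a & g[, 1] <= 12 * a &
          g[, 2] >= 2 * a & g[, 2] <= 12 * a
  expect_equal(dm$delta_i[deep], rep(1 / a^2, sum(deep)), tolerance = 1e-10)
  expect_equal(dm$area[deep], rep(a^2, sum(deep)), tolerance = 1e-10)
  # degenerate (cocircular) diagonal contacts are not adjacency
  degree <- tabulate(c(dm$edges[, 1], dm$edges[, 2]), nbins = nrow(g))
  expect_true(all(degree[deep] == 4))
})

test_that("densities scale as 1/c^2 under coordinate scaling", {
  pts <- withr::with_seed(41, cbind(runif(300) * 5000, runif(300) * 5000))
  d1 <- voronoi_densities(pts)
  d2 <- voronoi_densities(pts * 3)
  expect_equal(d2$delta_i, d1$delta_i / 9, tolerance = 1e-9)
})

test_that("CSR mean density matches the point density within 10%", {
  tab <- csr_table(10000, field = 10000, seed = 42)
  dm <- voronoi_densities(tab)
  expect_equal(dm$delta * 1e6, 100, tolerance = 0.1)
})

test_that("tessellation rejects degenerate inputs", {
  expect_error(voronoi_densities(cbind(1:3, 1:3)), "4 points")
  expect_error(voronoi_densities(cbind(1:10, rep(2, 10))), "collinear")
})

test_that("two disk clusters over diffuse background are segmented", {
  sim <- simulate_clustered_points(sim_cluster_config(
    n_clusters = 2, cluster_radius = 200, locs_per_cluster = 500,
    background_density = 20, loc_precision = 5, field_size = 10000,
    seed = 5))
  cs <- segment_clusters(sim$table)
  expect_equal(nrow(cs$clusters), 2L)
  expect_equal(cluster_diameters(cs), rep(400, 2), tolerance = 0.15)
  # count conservation: dense + non-dense interior + hull = total
  expect_equal(sum(cs$dense) + sum(!cs$dense & !cs$map$hull) +
                 sum(cs$map$hull & !cs$dense), cs$map$n)
  # members recover the true cluster assignment
  emitters <- sim$table$emitter[cs$members[[1]]]
  truth_cl <- sim$truth$cluster[emitters]
  main <- as.integer(names(which.max(table(truth_cl))))
  expect_gt(mean(truth_cl == main), 0.9)
  expect_error(segment_clusters(sim$table[0, ]), "4 points")
})

test_that("cluster diameters are scale-equivariant", {
  sim <- simulate_clustered_points(sim_cluster_config(
    n_clusters = 2, cluster_radius = 200, locs_per_cluster = 300,
    background_density = 20, loc_precision = 5, field_size = 10000,
    seed = 6))
  cs1 <- segment_clusters(sim$table)
  doubled <- sim$table
  doubled$x <- doubled$x * 2; doubled$y <- doubled$y * 2
  cs2 <- segment_clusters(doubled)
  expect_equal(cluster_diameters(cs2), 2 * cluster_diameters(cs1),
               tolerance = 1e-9)
})

test_that("a single-cell cluster has diameter 2*sqrt(area/pi)", {
  sim <- simulate_clustered_points(sim_cluster_config(
    n_clusters = 1, cluster_radius = 100, locs_per_cluster = 60,
    background_density = 5, loc_precision = 5, field_size = 6000,
    seed = 7))
  cs <- segment_clusters(sim$table, min_locs = 1)
  expect_true(all(abs(cs$clusters$diameter -
                        2 * sqrt(cs$clusters$area / pi)) < 1e-9))
})
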