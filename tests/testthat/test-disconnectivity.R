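test_that("a two-minimum system merges at the first level above its saddle", {
  db <- ktn_new(); ktn_put_minimum(db, 0, 0); ktn_put_minimum(db, 1, 0)
  ktn_put_ts(db, 2, 1, 2)
  tr <- build_disconnectivity_tree(db, levels = c(0.5, 1.5, 2.5))
  expect_equal(tr$n_basins, c(1L, 2L, 1L))
  expect_length(tr$roots, 1)
  root <- tr$roots[[1]]
  expect_equal(tr$levels[root$level], 2.5)
  expect_length(root$children, 2)
  expect_setequal(vapply(root$children, function(k) k$leaf, integer(1)),
                  c(1L, 2L))
})

test_that("a hand-built five-minimum chain reproduces the manual superbasin
           analysis", {
  # minima 1..5 at E = 0, .4, .1, .6, .2; chain TSs at 1.0, 2.0, 1.2, 3.0
  db <- ktn_new()
  for (e in c(0, 0.4, 0.1, 0.6, 0.2)) ktn_put_minimum(db, e, 0)
  ktn_put_ts(db, 1.0, 1, 2)
  ktn_put_ts(db, 2.0, 2, 3)
  ktn_put_ts(db, 1.2, 3, 4)
  ktn_put_ts(db, 3.0, 4, 5)
  tr <- build_disconnectivity_tree(db, levels = c(0.5, 1.5, 2.5, 3.5))
  # manual: at 0.5 minimum 4 (E = 0.6) is absent and the rest are separate;
  # at 1.5 the saddles at 1.0 and 1.2 give {1,2}, {3,4}, {5}; at 2.5 the
  # 2.0 saddle joins them into {1,2,3,4}; at 3.5 everything merges
  expect_equal(tr$n_basins, c(4L, 3L, 2L, 1L))
  txt <- tree_text(tr)
  expect_identical(txt[1], "basin@3.5 {1,2,3,4,5}")
  expect_true(any(grepl("basin@2.5 \\{1,2,3,4\\}", txt)))
  expect_true(any(grepl("basin@1.5 \\{1,2\\}", txt)))
  expect_true(any(grepl("basin@1.5 \\{3,4\\}", txt)))
})

test_that("superbasin counts are monotone and the lowest leaf is the global
           minimum", {
  spec <- synthetic_ktn_spec(n_funnels = 3, minima_per_funnel = 5,
                             intra_funnel_barrier = 1,
                             inter_funnel_barrier = 6, seed = 5)
  g <- generate_synthetic_ktn(spec)
  tr <- build_disconnectivity_tree(g$db, n_levels = 30)
  # counts never increase as the threshold rises past all minima
  above_all <- tr$levels > max(ktn_min_energies(g$db))
  expect_true(all(diff(tr$n_basins[above_all]) <= 0))
  expect_equal(min(g$db$min_energies),
               min(tr$leaf_energies))
})

test_that("a three-funnel network shows exactly three persistent stems", {
  spec <- synthetic_ktn_spec(n_funnels = 3, minima_per_funnel = 5,
                             intra_funnel_barrier = 1,
                             inter_funnel_barrier = 6, seed = 5)
  g <- generate_synthetic_ktn(spec)
  tr <- build_disconnectivity_tree(g$db, n_levels = 40)
  # once every funnel has internally merged but below the inter-funnel
  # barrier, exactly 3 basins persist over at least barrier-ratio levels
  complete <- tr$levels > max(ktn_min_energies(g$db))
  n3 <- sum(tr$n_basins == 3 & complete)
  expect_gte(n3, spec$inter_funnel_barrier / spec$intra_funnel_barrier)
  # and each of the 3 basins is one generator funnel
  l3 <- which(tr$n_basins == 3 & complete)[1]
  part <- lapply(split(seq_along(g$db$funnel), g$db$funnel), as.integer)
  lev <- tr$levels[l3]
  basins <- local({
    sub <- ktn_edges(g$db)
    sub <- sub[sub$energy <= lev, ]
    gg <- igraph::graph_from_data_frame(sub[, c("m1", "m2")],
                                        directed = FALSE,
                                        vertices = data.frame(
                                          name = as.character(ktn_min_ids(g$db))))
    comp <- igraph::components(gg)$membership
    lapply(split(names(comp), comp), as.integer)
  })
  key <- function(p) sort(vapply(p, function(b)
    paste(sort(b), collapse = ","), character(1)))
  expect_identical(key(basins), key(part))
})

test_that("the regrouped network at threshold 0 gives the raw-network tree", {
  db <- random_ktn(8, seed = 3)
  rg0 <- regroup_free_energy(db, 1, 0)
  t_raw <- build_disconnectivity_tree(db, n_levels = 12)
  t_rg <- build_disconnectivity_tree(rg0, n_levels = 12,
                                     energy_key = "potential")
  expect_identical(tree_text(t_raw), tree_text(t_rg))
})

test_that("free-energy trees use group free energies", {
  db <- random_ktn(8, seed = 3)
  rg <- regroup_free_energy(db, 1, 0.5)
  tr <- build_disconnectivity_tree(rg, n_levels = 10, energy_key = "free")
  expect_length(tr$leaf_energies, length(rg$groups))
  expect_error(build_disconnectivity_tree(db, energy_key = "free"),
               "regrouped")
})

test_that("rendering is deterministic and draws one stem per funnel", {
  db1 <- ktn_new(); ktn_put_minimum(db1, 0, 0)
  t1 <- build_disconnectivity_tree(db1, levels = c(1))
  f1 <- tempfile(fileext = ".svg")
  render_tree(t1, out = f1)
  svg1 <- readLines(f1)
  expect_equal(sum(grepl("<line", svg1)), 1 + sum(grepl("<line.*#555", svg1)))

  spec <- synthetic_ktn_spec(n_funnels = 3, minima_per_funnel = 4,
                             inter_funnel_barrier = 6, seed = 2)
  g <- generate_synthetic_ktn(spec)
  tr <- build_disconnectivity_tree(g$db, n_levels = 25)
  cmap <- setNames(seq_len(ktn_n_minima(g$db)) / ktn_n_minima(g$db),
                   ktn_min_ids(g$db))
  fa <- tempfile(fileext = ".svg"); fb <- tempfile(fileext = ".svg")
  render_tree(tr, color_map = cmap, out = fa)
  render_tree(tr, color_map = cmap, out = fb)
  expect_identical(readLines(fa), readLines(fb))
  # leaf stems carry the mapped colours
  svg <- readLines(fa)
  expect_true(any(grepl("stroke=\"#", svg)))
  expect_true(any(grepl("<rect", svg)))   # colour-bar legend present
})
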