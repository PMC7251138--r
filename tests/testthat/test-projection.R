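test_that("bipartite thresholding is strictly greater-than", {
  mdn <- makeMDN(data.frame(disease = "d1", mirna = paste0("m", 1:3),
                            weight = c(0.002, 0.001, 0.0005)))
  t1 <- suppressMessages(thresholdBipartite(mdn, 0.001))
  expect_equal(nrow(mdnEdges(t1)), 1)
  expect_equal(mdnEdges(t1)$mirna, "m1")
  expect_identical(mdnDiseases(t1), mdnDiseases(mdn))  # universe kept
  t0 <- suppressMessages(thresholdBipartite(mdn, 0))
  expect_equal(nrow(mdnEdges(t0)), 3)
  expect_error(suppressMessages(thresholdBipartite(mdn, 1)), "empty")
})

test_that("graph density follows the bipartite and unipartite formulas", {
  proj <- new("DiseaseProjection",
              nodes = paste0("d", 1:4),
              edges = data.frame(from = c("d1", "d1", "d2"),
                                 to = c("d2", "d3", "d3"),
                                 weight = c(1, 1, 1)))
  expect_equal(graphDensity(proj), 0.5)
  bip <- makeMDN(data.frame(
    disease = c("a1", "a1", "a2", "a2", "a3", "a3"),
    mirna = c("b1", "b2", "b2", "b3", "b3", "b4"),
    weight = rep(1, 6)),
    diseases = paste0("a", 1:3), mirnas = paste0("b", 1:4))
  expect_equal(graphDensity(bip), 0.5)
  full <- new("DiseaseProjection", nodes = c("x", "y"),
              edges = data.frame(from = "x", to = "y", weight = 2))
  expect_equal(graphDensity(full), 1)
})

test_that("density-matching picks the smallest workable threshold", {
  # 5 nodes, 5 edges with weights 5..1; target 0.2 allows <= 2 edges.
  # Candidate thresholds 1..5 give 4,3,2,1,0 surviving edges; 3 is the
  # smallest whose strict filter reaches density 0.2 (enumerated by hand).
  proj <- new("DiseaseProjection",
              nodes = paste0("d", 1:5),
              edges = data.frame(from = c("d1", "d2", "d3", "d4", "d1"),
                                 to = c("d2", "d3", "d4", "d5", "d3"),
                                 weight = c(5, 4, 3, 2, 1)))
  res <- matchDensityThreshold(proj, 0.2)
  expect_equal(res$threshold, 3)
  expect_equal(res$density, 0.2)

  easy <- matchDensityThreshold(proj, 0.9)
  expect_equal(easy$threshold, 0)
  expect_equal(easy$density, 0.5)

  flat <- new("DiseaseProjection",
              nodes = paste0("d", 1:5),
              edges = data.frame(from = c("d1", "d2", "d3"),
                                 to = c("d2", "d3", "d4"),
                                 weight = c(2, 2, 2)))
  expect_error(matchDensityThreshold(flat, 0.1), "unreachable")
})

test_that("thresholding after density-matching reproduces the achieved density", {
  set.seed(31)
  mdn <- makeMDN(data.frame(
    disease = rep(paste0("d", 1:6), each = 8),
    mirna = rep(paste0("m", 1:8), 6),
    weight = runif(48)))
  res <- matchDensityThreshold(mdn, 0.3)
  cut <- suppressMessages(thresholdBipartite(mdn, res$threshold))
  expect_equal(graphDensity(cut), res$density)

  proj <- projectDiseases(suppressMessages(thresholdBipartite(mdn, 0.5)))
  if (nrow(projectionEdges(proj)) > 1) {
    pres <- matchDensityThreshold(proj, 0.3)
    pcut <- thresholdProjection(proj, pres$threshold, drop_isolated = FALSE)
    expect_equal(graphDensity(pcut), pres$density)
  }
})

test_that("density is monotone non-increasing in the threshold", {
  set.seed(17)
  mdn <- makeMDN(data.frame(
    disease = rep(paste0("d", 1:5), each = 6),
    mirna = rep(paste0("m", 1:6), 5),
    weight = runif(30)))
  ths <- sort(unique(mdnEdges(mdn)$weight))[1:25]
  dens <- vapply(ths, function(t)
    graphDensity(suppressMessages(thresholdBipartite(mdn, t))), numeric(1))
  expect_true(all(diff(dens) <= 0))
})

test_that("disease projection counts shared partners", {
  mdn <- makeMDN(data.frame(
    disease = c("d1", "d1", "d2", "d2", "d3"),
    mirna = c("m1", "m2", "m2", "m3", "m4"),
    weight = rep(1, 5)))
  proj <- projectDiseases(mdn)
  expect_equal(projectionNodes(proj), c("d1", "d2", "d3"))  # d3 isolated
  expect_equal(projectionEdges(proj),
               data.frame(from = "d1", to = "d2", weight = 1))

  triple <- makeMDN(data.frame(
    disease = rep(c("d1", "d2"), each = 3),
    mirna = rep(paste0("m", 1:3), 2), weight = rep(1, 6)))
  expect_equal(projectionEdges(projectDiseases(triple))$weight, 3)
})

test_that("projection weights equal exhaustive pairwise intersections (oracle)", {
  set.seed(23)
  for (i in 1:20) {
    nd <- sample(3:10, 1); nm <- sample(3:12, 1)
    memb <- lapply(seq_len(nd), function(...)
      sample(paste0("m", 1:nm), sample(nm, 1)))
    names(memb) <- paste0("d", seq_len(nd))
    df <- data.frame(disease = rep(names(memb), lengths(memb)),
                     mirna = unlist(memb), weight = 1)
    proj <- projectDiseases(makeMDN(df))
    e <- projectionEdges(proj)
    got <- setNames(e$weight, paste(e$from, e$to))
    for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
      key <- paste(paste0("d", a), paste0("d", b))
      expected <- length(intersect(memb[[a]], memb[[b]]))
      if (expected == 0) expect_false(key %in% names(got))
      else expect_equal(unname(got[key]), expected)
    }
    expect_true(all(e$from < e$to))  # symmetry stored canonically
  }
})

test_that("gene-space projection works on a disease-gene map", {
  dg <- list(d1 = c("g1", "g2", "g3"), d2 = c("g2", "g3"), d3 = "g9")
  proj <- projectDiseases(dg)
  expect_equal(projectionEdges(proj),
               data.frame(from = "d1", to = "d2", weight = 2))
  expect_error(projectDiseases(list()), "empty")
})

test_that("projection thresholding is strict and removes isolated nodes", {
  proj <- new("DiseaseProjection",
              nodes = paste0("d", 1:5),
              edges = data.frame(from = c("d1", "d2", "d3"),
                                 to = c("d2", "d3", "d4"),
                                 weight = c(8, 7, 3)))
  cut <- thresholdProjection(proj, 7)
  expect_equal(nrow(projectionEdges(cut)), 1)
  expect_equal(projectionNodes(cut), c("d1", "d2"))  # d3,d4,d5 dropped
  ident <- thresholdProjection(proj, 0)
  expect_equal(nrow(projectionEdges(ident)), 3)
  expect_equal(projectionNodes(ident), paste0("d", 1:4))  # d5 was isolated
  expect_error(thresholdProjection(proj, 99), "empty")
})
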