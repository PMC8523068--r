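test_that("hierarchical seeding recovers disjoint correlated blocks", {
  blocks <- list(
    list(genes = sprintf("g%04d", 1:20), hot_samples = 1:10),
    list(genes = sprintf("g%04d", 21:40), hot_samples = 11:20),
    list(genes = sprintf("g%04d", 41:60), hot_samples = 21:30))
  expr <- planted_expr(60, 30, blocks, seed = 2)
  seeds <- seed_clusters(expr, min_size = 10, max_size = 100)
  expect_length(seeds$seeds, 3)
  # each block is matched by a distinct seed (fragmentation from the
  # smallest-height tie-break keeps matches above 0.7; ISA refinement is
  # what sharpens seeds into exact modules)
  matched <- vapply(blocks, function(b)
    which.max(vapply(seeds$seeds, jaccard, numeric(1), b = b$genes)),
    integer(1))
  scores <- vapply(blocks, function(b)
    max(vapply(seeds$seeds, jaccard, numeric(1), b = b$genes)), numeric(1))
  expect_length(unique(matched), 3)
  expect_true(all(scores >= 0.7))
  expect_error(seed_clusters(planted_expr(8, 10, list(), seed = 1),
                             min_size = 10, max_size = 100),
               "too few genes")
})

test_that("seed expansion multiplies seeds with union semantics, reproducibly", {
  expr <- planted_expr(150, 10, list(), seed = 3)
  genes <- rownames(expr$values)
  base <- structure(list(seeds = list(genes[1:5], genes[6:12]),
                         provenance = list()), class = "seed_set")
  out <- expand_seeds(base, genes, n_random = 100, n_repeats = 3,
                      rng_seed = 9)
  expect_length(out$seeds, 6)
  sizes <- lengths(out$seeds)
  # union semantics: size = |base| + 100 - |overlap|, never exceeding either bound
  expect_true(all(sizes >= 100 & sizes <= 112))
  expect_true(all(vapply(out$seeds, anyDuplicated, 1L) == 0))
  # identity case
  same <- expand_seeds(base, genes, n_random = 0, n_repeats = 1, rng_seed = 1)
  expect_identical(same$seeds, base$seeds)
  # reproducibility
  again <- expand_seeds(base, genes, n_random = 100, n_repeats = 3,
                        rng_seed = 9)
  expect_identical(out$seeds, again$seeds)
})

test_that("a perfectly coherent planted block is an ISA fixed point", {
  blocks <- list(list(genes = sprintf("g%04d", 1:25), hot_samples = 1:8))
  expr <- planted_expr(300, 40, blocks, shift = 6, noise = 0.05, seed = 4)
  seeds <- structure(list(seeds = list(blocks[[1]]$genes),
                          provenance = list()), class = "seed_set")
  mods <- isa_refine(expr, seeds, min_support = 0)
  expect_length(mods, 1)
  expect_gte(jaccard(mods[[1]]$genes, blocks[[1]]$genes), 0.95)
})

test_that("ISA refinement recovers planted blocks from noisy random seeds", {
  blocks <- lapply(1:5, function(i)
    list(genes = sprintf("g%04d", (i - 1) * 30 + 1:30),
         hot_samples = (i - 1) * 8 + 1:8))
  expr <- planted_expr(700, 40, blocks, shift = 5, noise = 0.2, seed = 5)
  set.seed(10)
  noisy <- structure(list(
    seeds = replicate(200, sample(rownames(expr$values), 40),
                      simplify = FALSE),
    provenance = list()), class = "seed_set")
  mods <- isa_refine(expr, noisy)
  expect_length(mods, 5)
  best <- vapply(blocks, function(b)
    max(vapply(mods, function(m) jaccard(m$genes, b$genes), numeric(1))),
    numeric(1))
  expect_true(all(best >= 0.9))
  # modules are sorted by size and renumbered from 1
  expect_identical(vapply(mods, function(m) m$module_id, 1L),
                   seq_along(mods))
  expect_true(all(diff(vapply(mods, function(m) length(m$genes), 1L)) <= 0))
})

test_that("refinement output is invariant to seed list order", {
  blocks <- list(list(genes = sprintf("g%04d", 1:20), hot_samples = 1:6),
                 list(genes = sprintf("g%04d", 21:45), hot_samples = 7:12))
  expr <- planted_expr(250, 24, blocks, seed = 6)
  set.seed(11)
  seeds <- replicate(60, sample(rownames(expr$values), 30), simplify = FALSE)
  s1 <- structure(list(seeds = seeds, provenance = list()),
                  class = "seed_set")
  s2 <- structure(list(seeds = rev(seeds), provenance = list()),
                  class = "seed_set")
  m1 <- isa_refine(expr, s1)
  m2 <- isa_refine(expr, s2)
  expect_identical(lapply(m1, function(m) m$genes),
                   lapply(m2, function(m) m$genes))
})

test_that("raising the gene threshold never grows the recovered modules", {
  blocks <- list(list(genes = sprintf("g%04d", 1:30), hot_samples = 1:8))
  expr <- planted_expr(300, 30, blocks, shift = 4, noise = 0.4, seed = 8)
  seeds <- structure(list(seeds = list(blocks[[1]]$genes),
                          provenance = list()), class = "seed_set")
  sizes <- vapply(c(1.0, 1.5, 2.0, 2.5), function(th) {
    m <- isa_refine(expr, seeds, gene_threshold = th, min_support = 0)
    if (length(m) == 0) 0L else length(m[[1]]$genes)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("pure-noise matrices yield (almost) no supported modules", {
  expr <- planted_expr(400, 40, list(), seed = 12)
  set.seed(13)
  n_seeds <- 150
  seeds <- structure(list(
    seeds = replicate(n_seeds, sample(rownames(expr$values), 40),
                      simplify = FALSE),
    provenance = list()), class = "seed_set")
  mods <- suppressWarnings(isa_refine(expr, seeds))
  # seeds whose fixed point survives into the module list, as a fraction
  retained <- if (length(mods) == 0) 0 else
    sum(vapply(mods, function(m) m$support, numeric(1)))
  expect_lt(retained, 0.05)
})

test_that("Jaccard-closure merging is idempotent", {
  sets <- list(letters[1:10], letters[2:10], letters[15:20], letters[16:21])
  once <- modact:::merge_gene_sets(sets, 0.7)
  twice <- modact:::merge_gene_sets(unclass(once), 0.7)
  expect_identical(unname(unclass(once)[seq_along(once)]),
                   unname(unclass(twice)[seq_along(twice)]))
})

test_that("modules round-trip through the module_id/gene_id TSV dialect", {
  blocks <- list(list(genes = sprintf("g%04d", 1:15), hot_samples = 1:5))
  expr <- planted_expr(100, 15, blocks, seed = 14)
  seeds <- structure(list(seeds = list(blocks[[1]]$genes),
                          provenance = list()), class = "seed_set")
  mods <- isa_refine(expr, seeds, min_support = 0)
  f <- tempfile(fileext = ".tsv")
  write_modules(mods, f)
  back <- read_modules(f)
  expect_identical(lapply(back, function(m) m$genes),
                   lapply(mods, function(m) m$genes))
  unlink(f)
})
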