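test_that("the objective evaluates the summed positive cluster gains", {
  # two reads, one variant, deltas (+2, -3)
  Pu <- matrix(c(2, -3), nrow = 2, dimnames = list(c("r1", "r2"), NULL))
  expect_equal(cluster_objective(Pu, assignment = c(r1 = 1L, r2 = 2L)), 2)
  expect_equal(cluster_objective(Pu, assignment = c(r1 = 1L, r2 = 1L)), 0)
  # empty variant set: objective 0 for every assignment
  P0 <- matrix(numeric(0), nrow = 2, ncol = 0,
               dimnames = list(c("r1", "r2"), NULL))
  expect_equal(cluster_objective(P0, assignment = c(r1 = 1L, r2 = 2L)), 0)
  expect_error(cluster_objective(Pu, assignment = c(r1 = 1L)), "cover")
})

test_that("the objective is non-negative and label-permutation invariant", {
  set.seed(1)
  for (rep in 1:20) {
    Pu <- matrix(rnorm(8 * 3, sd = 3), 8, 3,
                 dimnames = list(paste0("r", 1:8), NULL))
    asg <- setNames(sample(3, 8, replace = TRUE), paste0("r", 1:8))
    obj <- cluster_objective(Pu, assignment = asg)
    expect_gte(obj, 0)
    perm <- sample(3)
    expect_equal(cluster_objective(Pu, assignment = setNames(perm[asg], names(asg))),
                 obj)
  }
})

test_that("K = 1 returns a single cluster with the summed objective", {
  Pu <- matrix(c(2, 2, -1, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  cl <- cluster_reads(Pu, K = 1)
  expect_equal(unname(cl$assignment), c(1L, 1L))
  expect_equal(cl$objective, sum(pmax(colSums(Pu), 0)))
  expect_error(cluster_reads(Pu, K = 3), "clusters")
})

test_that("the sampler attains the enumerated optimum on small instances", {
  set.seed(7)
  hits <- 0
  runs <- 40
  for (s in seq_len(runs)) {
    N <- sample(5:8, 1)
    K <- sample(2:3, 1)
    # planted structure plus noise
    grp <- sample(K, N, replace = TRUE)
    Pu <- matrix(rnorm(N * 3), N, 3, dimnames = list(paste0("r", 1:N), NULL))
    for (u in 1:3) Pu[, u] <- Pu[, u] + ifelse(grp == (u %% K) + 1, 2, -2)
    opt <- enumerate_optimum(Pu, K)
    fit <- cluster_reads(Pu, K = K, config = clustering_config(seed = s))
    expect_equal(cluster_objective(Pu, assignment = fit$assignment), fit$objective)
    if (fit$objective >= opt - 1e-9) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
})

test_that("the stored objective always matches its assignment", {
  set.seed(3)
  mk <- make_copies(500, 2, 1, seed = 31)
  reads <- copy_reads(mk$copies, 10, 0.1, seed = 32)
  segs <- oriented_segs(reads)
  P <- perturbation_matrix(mk$copies[1], segs, band = 60)
  U <- collect_variants(P)
  cl <- cluster_reads(P, U, K = 2, clustering_config(seed = 4))
  expect_equal(cluster_objective(cl$deltas, assignment = cl$assignment),
               cl$objective, tolerance = 1e-9)
})

test_that("the Rand index counts agreeing pairs", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1.0)  # labels renamed
  # truth {a,b}{c,d} vs predicted {a,c}{b,d}: 2 of 6 pairs agree
  expect_equal(rand_index(setNames(c(1, 1, 2, 2), letters[1:4]),
                          setNames(c(1, 2, 1, 2), letters[1:4])), 2 / 6)
  # all singletons vs one cluster: no pair agrees
  expect_equal(rand_index(rep(1, 4), 1:4), 0)
  expect_error(rand_index(1, 1), ">= 2")
  expect_error(rand_index(setNames(1:2, c("a", "b")),
                          setNames(1:2, c("a", "c"))), "different")
})

test_that("neighbor correction reassigns a misplaced read", {
  # three chunks sharing six reads; the read r1 is misassigned on chunk B
  ids <- paste0("r", 1:6)
  truthg <- c(1L, 1L, 1L, 2L, 2L, 2L)
  mkcl <- function(asg, Pu) {
    cl <- list(assignment = setNames(asg, ids), K = 2L,
               objective = cluster_objective(Pu, assignment = setNames(asg, ids)),
               deltas = Pu)
    class(cl) <- "read_clustering"
    cl
  }
  # deltas neutral on B (no information), informative on A and C
  PuAC <- matrix(ifelse(truthg == 1, 3, -3), 6, 1, dimnames = list(ids, NULL))
  PuB <- matrix(0, 6, 1, dimnames = list(ids, NULL))
  clusterings <- list(A = mkcl(truthg, PuAC),
                      B = mkcl(c(2L, 1L, 1L, 2L, 2L, 2L), PuB),
                      C = mkcl(truthg, PuAC))
  aligns <- do.call(rbind, lapply(c("A", "B", "C"), function(cid)
    data.frame(chunk_id = cid, read_id = ids, read_start = 0, read_end = 2000,
               strand = "+", edit_distance = 0, identity = 1,
               stringsAsFactors = FALSE)))
  out <- correct_with_neighbors(clusterings, aligns, min_shared = 3)
  expect_equal(unname(out$B$assignment["r1"]),
               unname(out$B$assignment["r2"]))
  # consistent clusterings are a fixed point
  clusterings2 <- list(A = mkcl(truthg, PuAC), B = mkcl(truthg, PuB),
                       C = mkcl(truthg, PuAC))
  out2 <- correct_with_neighbors(clusterings2, aligns, min_shared = 3)
  expect_identical(lapply(out2, `[[`, "assignment"),
                   lapply(clusterings2, `[[`, "assignment"))
  # an isolated chunk is untouched
  iso <- list(A = mkcl(truthg, PuAC))
  expect_identical(correct_with_neighbors(iso, aligns[aligns$chunk_id == "A", ]),
                   iso)
})
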