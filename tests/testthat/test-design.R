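test_that("random assignment is uniform over bases and pairs", {
  single <- list(kind = "single", pos = 1L)
  paired <- list(kind = "paired", pos = c(1L, 5L))
  set.seed(20)
  draws_s <- replicate(60000, random_assignment(single)$value)
  freq_s <- table(draws_s) / length(draws_s)
  expect_equal(sort(names(freq_s)), c("A", "C", "G", "U"))
  expect_true(all(abs(freq_s - 0.25) < 0.01))
  expect_gt(stats::chisq.test(table(draws_s))$p.value, 0.001)

  draws_p <- replicate(60000, random_assignment(paired)$value)
  freq_p <- table(draws_p) / length(draws_p)
  expect_equal(length(freq_p), 6L)
  expect_true(all(abs(freq_p - 1 / 6) < 0.01))
  expect_gt(stats::chisq.test(table(draws_p))$p.value, 0.001)

  # seeded determinism
  set.seed(99); a <- replicate(50, random_assignment(paired)$value)
  set.seed(99); b <- replicate(50, random_assignment(paired)$value)
  expect_identical(a, b)
})

test_that("initial sequences hit the GC target to within one paired placement", {
  ts <- parse_dotbracket("((....))")
  set.seed(5)
  for (rep in 1:1000) {
    s <- generate_initial(ts, list(), alpha_star = 0.5)
    expect_true(gc_count_of(s) %in% c(4L, 5L), info = s)
  }
  # alpha* = 0: pure A/U sequence
  set.seed(6)
  s0 <- generate_initial(ts, list(), alpha_star = 0)
  expect_false(grepl("[GC]", s0))
  # paired sites receive complementary pairs
  set.seed(7)
  for (rep in 1:50) {
    s <- generate_initial(ts, list(), alpha_star = 0.5)
    b <- strsplit(s, "")[[1]]
    expect_true(paste0(b[1], b[8]) %in% c("AU", "UA", "GC", "CG"))
    expect_true(paste0(b[2], b[7]) %in% c("AU", "UA", "GC", "CG"))
  }
})

test_that("essential events are copied verbatim and never overwritten", {
  ts <- parse_dotbracket("((....))")
  sites <- target_sites(ts)
  # fully determined: every site essential
  set.seed(1)
  essential <- lapply(sites, random_assignment)
  s <- generate_initial(ts, essential, alpha_star = 0.5)
  expect_identical(s, generate_initial(ts, essential, alpha_star = 0.5))
  bases <- strsplit(s, "")[[1]]
  for (e in essential) {
    val <- strsplit(e$value, "")[[1]]
    expect_identical(bases[e$site$pos], val)
  }
  # partial essentials survive generate_initial and many local updates
  ess <- list(list(site = sites[[1]], value = "GC"),
              list(site = sites[[3]], value = "A"))
  ess_pos <- c(sites[[1]]$pos, sites[[3]]$pos)
  set.seed(2)
  for (rep in 1:50) {
    s <- generate_initial(ts, ess, alpha_star = 0.5)
    b0 <- strsplit(s, "")[[1]]
    for (step in 1:5) {
      pred <- reference_fold(s)$structure
      s <- local_update(s, ts, pred, ess)
    }
    b <- strsplit(s, "")[[1]]
    expect_identical(b[ess_pos], b0[ess_pos])
    expect_identical(b[sites[[1]]$pos], c("G", "C"))
    expect_identical(b[sites[[3]]$pos], "A")
  }
})

test_that("rule (i) rewrites unformed target pairs as on the worked 13-nt example", {
  ts <- parse_dotbracket(".(((.....)).)")
  # bases chosen so pairs (3,11) and (4,10) hold A/U yet are unpaired in the
  # prediction, while (2,13) holds G-C and did form
  seq <- "AGAACACAAUUAC"
  predicted <- ".(..........)"   # pair (2,13) only
  set.seed(3)
  for (rep in 1:100) {
    out <- local_update(seq, ts, predicted, list())
    b <- strsplit(out, "")[[1]]
    # target pairs (3,11) and (4,10) were not predicted: rule (i) fires
    expect_true(paste0(b[3], b[11]) %in% c("AU", "UA", "CG", "GC"))
    expect_true(paste0(b[4], b[10]) %in% c("AU", "UA", "CG", "GC"))
    # pair (2,13) is both a target and a predicted pair: untouched
    expect_identical(b[c(2, 13)], c("G", "C"))
  }
})

test_that("rule (ii) breaks spurious pairs and conserves GC count", {
  # an all-unpaired target makes every predicted pair spurious, so a pass
  # applies rule (ii) alone; folding the sequence first guarantees the
  # spurious pairs hold admissible base pairs
  n <- 15
  ts <- parse_dotbracket(strrep(".", n))
  breaks <- list(AU = c("AA", "UU"), UA = c("AA", "UU"),
                 GC = c("CC", "GG"), CG = c("CC", "GG"),
                 GU = c("AC", "CA", "AG", "GA", "CU", "UC"),
                 UG = c("AC", "CA", "AG", "GA", "CU", "UC"))
  set.seed(4)
  for (rep in 1:300) {
    s <- random_rna(n)
    pred <- reference_fold(s)$structure
    out <- local_update(s, ts, pred, list())
    expect_equal(gc_count_of(out), gc_count_of(s))
    b0 <- strsplit(s, "")[[1]]
    b <- strsplit(out, "")[[1]]
    pp <- parse_dotbracket(pred)$pairs
    for (p in seq_len(nrow(pp))) {
      i <- pp[p, 1]; j <- pp[p, 2]
      was <- paste0(b0[i], b0[j])
      expect_true(paste0(b[i], b[j]) %in% breaks[[was]],
                  info = sprintf("%s pair (%d,%d) in %s", was, i, j, s))
    }
    # untouched positions keep their bases
    touched <- as.integer(pp)
    keep <- setdiff(seq_len(n), touched)
    expect_identical(b[keep], b0[keep])
  }
})

test_that("the wobble-pair break reaches all six GC-neutral options", {
  # spurious predicted pair (1,6) carries G-U; the target is unpaired there
  ts2 <- parse_dotbracket(".......")
  set.seed(8)
  seen <- character(0)
  for (rep in 1:300) {
    out <- local_update("GAAAAUA", ts2, "(....).", list())
    b <- strsplit(out, "")[[1]]
    seen <- c(seen, paste0(b[1], b[6]))
    expect_equal(gc_count_of(out), 1L)  # the lone G or C survives somewhere
  }
  expect_setequal(unique(seen), c("AC", "CA", "AG", "GA", "CU", "UC"))
})

test_that("playouts consume exactly one fold per candidate and stop early", {
  ts <- parse_dotbracket("((((....))))")
  p <- reward_params()
  set.seed(10)
  be <- fold_backend("reference")
  cands <- simulate_playout(list(), ts, p, k = 1, backend = be)
  expect_length(cands, 1L)
  expect_equal(be$calls, 1L)

  be2 <- fold_backend("reference")
  cands <- simulate_playout(list(), ts, p, k = 50, backend = be2)
  expect_lte(length(cands), 50L)
  expect_equal(be2$calls, length(cands))
  if (cands[[length(cands)]]$reward$d == 0)
    expect_true(all(vapply(cands[-length(cands)],
                           function(cc) cc$reward$d > 0, logical(1))))
})

test_that("mean structural distance does not increase over playout steps", {
  ts <- parse_dotbracket("(((((.....))))).....")
  p <- reward_params()
  set.seed(123)
  d_first <- c(); d_last <- c()
  for (rep in 1:200) {
    be <- fold_backend("reference")
    cands <- simulate_playout(list(), ts, p, k = 10, backend = be)
    d_first <- c(d_first, cands[[1]]$reward$d)
    d_last <- c(d_last, cands[[length(cands)]]$reward$d)
  }
  expect_lte(mean(d_last), mean(d_first))
})
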