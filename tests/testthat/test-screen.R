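make_metrology <- function(n, distance, diameter) {
  data.frame(protein_id = sprintf("P%02d", seq_len(n)), n_cells = 20L,
             mean_distance_nm = distance, sem_distance_nm = 5,
             mean_pseudo_diameter_nm = diameter, sem_pseudo_diameter_nm = 5)
}

test_that("the inclusion gate removes exactly the out-of-window candidates", {
  bl <- control_baselines(150, 450, 110)
  # 31 candidates, exactly one proximal to the distal-end control
  distances <- c(100, seq(200, 440, length.out = 30))
  m <- make_metrology(31, distances, 250)
  gated <- apply_inclusion_gate(m, bl)
  expect_equal(sum(gated$gate_verdict == "included"), 30)
  expect_equal(as.character(gated$gate_verdict[1]), "excluded_proximal")
  # the diameter gate removes none when all candidates are wider
  expect_equal(sum(gated$gate_verdict == "excluded_narrow"), 0)
  # partition: every candidate gets exactly one verdict
  expect_equal(sum(table(gated$gate_verdict)), 31)
})

test_that("boundary candidates are excluded under strict inequalities", {
  bl <- control_baselines(150, 450, 110)
  m <- make_metrology(3, c(150, 450, 300), c(250, 250, 110))
  v <- as.character(apply_inclusion_gate(m, bl)$gate_verdict)
  expect_equal(v, c("excluded_proximal", "excluded_distal", "excluded_narrow"))
  m2 <- make_metrology(1, NA_real_, 250)
  expect_warning(g2 <- apply_inclusion_gate(m2, bl), "unclassified")
  expect_equal(as.character(g2$gate_verdict), "unclassified")
  expect_error(control_baselines(450, 150, 110), "below")
})

obs <- function(red, green, prob = FALSE)
  data.frame(red_focus_count = red, green_focus_count = green,
             green_on_probasal = prob)

test_that("recruitment timing classification follows the focus-count logic", {
  # every pre-duplication cell already has two green foci: early recruitment
  early <- rbind(obs(rep(2L, 10), rep(2L, 10)), obs(rep(4L, 6), rep(2L, 6)))
  expect_equal(classify_recruitment(early), "before_duplication")
  # the second green focus appears only at four red foci: late recruitment
  late <- rbind(obs(rep(2L, 10), rep(1L, 10)), obs(rep(4L, 6), rep(2L, 6)))
  expect_equal(classify_recruitment(late), "after_duplication")
  # a third of S-phase cells with probasal signal clears min_fraction 0.25
  prob <- rbind(obs(rep(2L, 8), rep(2L, 8), TRUE),
                obs(rep(4L, 9), rep(2L, 9), rep(c(TRUE, FALSE, FALSE), 3)))
  expect_equal(classify_recruitment(prob, min_fraction = 0.25), "probasal")
  # single-stage observations cannot be classified
  expect_warning(r <- classify_recruitment(obs(rep(2L, 12), rep(1L, 12))),
                 "spanning")
  expect_equal(r, "unclassified")
})

test_that("recruitment calls are invariant to observation order", {
  set.seed(4)
  mixed <- rbind(obs(rep(2L, 12), rep(c(2L, 1L), 6)),
                 obs(rep(4L, 8), rep(2L, 8)))
  base <- classify_recruitment(mixed)
  for (i in 1:5)
    expect_equal(classify_recruitment(mixed[sample(nrow(mixed)), ]), base)
})

hit <- function(q, s, e, b) data.frame(query_id = q, subject_id = s,
                                       e_value = e, bitscore = b)

test_that("reciprocal best hits resolve toy tables exactly", {
  expect_equal(nrow(reciprocal_best_hits(hit(character(), character(),
                                             numeric(), numeric()),
                                         hit("x", "y", 1e-9, 50))), 0)
  ab <- hit(c("a1", "a1", "a2"), c("b1", "b2", "b1"),
            c(1e-20, 1e-3, 1e-8), c(200, 40, 90))
  ba <- hit(c("b1", "b2"), c("a1", "a1"), c(1e-18, 1e-2), c(190, 30))
  out <- reciprocal_best_hits(ab, ba)
  expect_equal(out$id_a, "a1")
  expect_equal(out$id_b, "b1")
  # one side at E = 1e-4 fails the acceptance threshold
  ba2 <- hit("b1", "a1", 1e-4, 190)
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0)
})

test_that("RBH matches the brute-force oracle on random small genomes", {
  set.seed(11)
  for (rep in 1:15) {
    na <- sample(3:20, 1); nb <- sample(3:20, 1)
    ga <- sprintf("a%02d", 1:na); gb <- sprintf("b%02d", 1:nb)
    nh <- sample(10:40, 1)
    ab <- hit(sample(ga, nh, TRUE), sample(gb, nh, TRUE),
              10^runif(nh, -30, 0), runif(nh, 20, 300))
    nh2 <- sample(10:40, 1)
    ba <- hit(sample(gb, nh2, TRUE), sample(ga, nh2, TRUE),
              10^runif(nh2, -30, 0), runif(nh2, 20, 300))
    mine <- reciprocal_best_hits(ab, ba)
    oracle <- brute_force_rbh(ab, ba)
    expect_equal(mine$id_a, oracle$id_a)
    expect_equal(mine$id_b, oracle$id_b)
  }
})

test_that("malformed alignment rows are skipped with a count", {
  f <- tempfile(fileext = ".tsv")
  rows <- c(paste(c("a1", "b1", 90, 100, 5, 1, 1, 100, 1, 100, "1e-30", 250),
                  collapse = "\t"),
            paste(c("a2", "b2", 80, 90, 9, 2, 1, 90, 1, 90, "oops", 120),
                  collapse = "\t"))
  writeLines(rows, f)
  expect_message(h <- read_hit_table(f), "1 malformed")
  expect_equal(nrow(h), 1)
  expect_equal(h$e_value, 1e-30)
  unlink(f)
})

test_that("class-count summaries conserve totals and handle empty input", {
  tab <- tfp_screen_table()
  s <- summarize_classes(tab)
  expect_equal(sum(s$recruitment_class), s$total)
  expect_equal(sum(s$rnai_phenotype), s$total)
  empty <- summarize_classes(tab[0, ])
  expect_equal(empty$total, 0)
  expect_true(all(empty$recruitment_class == 0))
  one_each <- data.frame(recruitment_class = c("before_duplication",
                                               "after_duplication",
                                               "probasal"))
  expect_equal(unname(summarize_classes(one_each)$recruitment_class[1:3]),
               c(1L, 1L, 1L))
})

test_that("alpha-helix length arithmetic is exact and linear", {
  expect_identical(helix_length(0), 0)
  expect_equal(helix_length(360), 54)   # 100 turns of 0.54 nm
  n <- c(100, 500, 900)
  expect_equal(helix_length(2 * n), 2 * helix_length(n))
  expect_error(helix_length(-5), "nonnegative")
  expect_error(helix_length(100, residues_per_turn = 0), "positive")
})
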