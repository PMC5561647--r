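make_records <- function(n_ctrl = 6, seed = 3) {
  set.seed(seed)
  ids <- sprintf("A%02d", seq_len(n_ctrl + 4))
  groups <- c(rep("VEH/V", n_ctrl), rep("CORT/V", 4))
  do.call(rbind, lapply(1:2, function(s) {
    data.frame(animal_id = ids, group = groups, session = s,
               epm_open_time_s = rnorm(length(ids), 60, 20),
               epm_open_entries = round(rnorm(length(ids), 10, 3)),
               nsf_latency_s = rlnorm(length(ids), log(150), 0.5),
               nsf_food_mg_per_g = rnorm(length(ids), 8, 2),
               st_grooming_s = rnorm(length(ids), 80, 25),
               stringsAsFactors = FALSE)
  }))
}

test_that("z-scores are zero at the control mean and follow the sign convention", {
  rec <- make_records()
  z <- zscore_measures(rec)

  # an animal sitting exactly at the control mean scores zero
  ctrl1 <- rec[rec$group == "VEH/V" & rec$session == 1, ]
  probe <- ctrl1[1, ]
  probe$animal_id <- "PROBE"
  probe$group <- "CORT/V"
  for (m in c("epm_open_time_s", "st_grooming_s", "nsf_latency_s")) {
    probe[[m]] <- mean(ctrl1[[m]])
  }
  z2 <- zscore_measures(rbind(rec, probe))
  zp <- z2[z2$animal_id == "PROBE", ]
  expect_equal(zp$z[zp$measure == "epm_open_time_s"], 0)
  expect_equal(zp$z[zp$measure == "nsf_latency_s"], 0)

  # one sd less grooming than controls means +1 emotionality (sign -1)
  probe$st_grooming_s <- mean(ctrl1$st_grooming_s) - sd(ctrl1$st_grooming_s)
  z3 <- zscore_measures(rbind(rec, probe))
  expect_equal(z3$z[z3$animal_id == "PROBE" &
                      z3$measure == "st_grooming_s"], 1)

  # control group standardizes itself: mean 0, sd 1 per measure
  zc <- z[z$group == "VEH/V" & z$session == 1, ]
  for (m in unique(zc$measure)) {
    expect_equal(mean(zc$z[zc$measure == m]), 0, tolerance = 1e-9)
    expect_equal(sd(zc$z[zc$measure == m]), 1, tolerance = 1e-9)
  }
})

test_that("control cohort composite emotionality is zero by construction", {
  rec <- make_records(n_ctrl = 11, seed = 8)
  sc <- emotionality(zscore_measures(rec))
  for (s in 1:2) {
    expect_lt(abs(mean(sc$emotionality[sc$group == "VEH/V" &
                                         sc$session == s])), 1e-9)
  }
})

test_that("degenerate or missing references raise informative errors", {
  rec <- make_records()
  rec$st_grooming_s[rec$group == "VEH/V"] <- 50  # zero control spread
  expect_error(zscore_measures(rec), "st_grooming_s")

  rec2 <- make_records()
  rec2$nsf_latency_s[3] <- NA
  expect_error(zscore_measures(rec2), "missing")

  rec3 <- make_records()[, -which(names(make_records()) == "st_grooming_s")]
  expect_error(zscore_measures(rec3), "st_grooming_s")
})

test_that("two-stage averaging weights tests equally, not measures", {
  z <- data.frame(
    animal_id = "A1", group = "CORT/Flx", session = 1,
    test = c("EPM", "EPM", "NSF", "ST"),
    measure = c("epm_open_time_s", "epm_open_entries", "nsf_latency_s",
                "st_grooming_s"),
    z = c(1.0, 3.0, 2.0, 0.0), stringsAsFactors = FALSE
  )
  sc <- emotionality(z)
  expect_equal(sc$z_epm, 2.0)
  expect_equal(sc$z_nsf, 2.0)
  expect_equal(sc$z_st, 0.0)
  expect_equal(sc$emotionality, 4 / 3)  # not the flat mean 1.5

  # permuting measures within a test changes nothing
  sc2 <- emotionality(z[c(2, 1, 4, 3), ])
  expect_equal(sc2$emotionality, sc$emotionality)

  # all-zero z gives a zero composite
  z0 <- z
  z0$z <- 0
  expect_equal(emotionality(z0)$emotionality, 0)

  # a test with no scored measure is an error naming animal and test
  expect_error(emotionality(z[z$test != "ST", ]), "ST")
})

test_that("composite is affine-invariant in the raw measures", {
  rec <- make_records(seed = 21)
  sc <- emotionality(zscore_measures(rec))
  rec2 <- rec
  rec2$epm_open_time_s <- 3.7 * rec2$epm_open_time_s + 12
  rec2$nsf_latency_s <- 0.5 * rec2$nsf_latency_s + 100
  sc2 <- emotionality(zscore_measures(rec2))
  expect_equal(sc2$emotionality, sc$emotionality, tolerance = 1e-12)
})

test_that("50% rule classifies response and reports the cohort rate", {
  sc <- make_scores(c("A1", "A2"), pre = c(2.0, 2.0), post = c(0.9, 1.2))
  lab <- classify_response(sc)
  expect_equal(lab$label[lab$animal_id == "A1"], "responder")     # 55% drop
  expect_equal(lab$label[lab$animal_id == "A2"], "non_responder") # 40% drop

  # 30 responders among 46 treated -> 65.2%
  pre <- rep(2, 46)
  post <- c(rep(0.8, 30), rep(1.8, 16))
  lab46 <- classify_response(make_scores(sprintf("B%02d", 1:46), pre, post))
  expect_equal(responder_rate(lab46), 65.2)
  expect_equal(sum(lab46$label == "responder"), 30)
})

test_that("classification is monotone in the post score", {
  pre <- 2
  posts <- seq(2.5, -1, by = -0.1)
  labs <- vapply(posts, function(p) {
    classify_response(make_scores("A1", pre, p))$label
  }, character(1))
  flips <- rle(labs)$values
  expect_equal(flips, c("non_responder", "responder"))
})

test_that("non-positive baselines become not_applicable but stay in the denominator", {
  sc <- make_scores(c("A1", "A2", "A3"), pre = c(2, -0.5, 2),
                    post = c(0.5, -1, 1.5))
  expect_warning(lab <- classify_response(sc), "baseline")
  expect_equal(lab$label[lab$animal_id == "A2"], "not_applicable")
  expect_equal(responder_rate(lab), round(100 / 3, 1))
  lab2 <- suppressWarnings(
    classify_response(sc, na_in_denominator = FALSE))
  expect_equal(responder_rate(lab2), 50)
})

test_that("most-affected selection is top-k, deterministic, and validated", {
  sc <- rbind(
    make_scores(c("C1", "C2", "C3"), pre = c(2, 2, 2),
                post = c(2.1, 0.3, 1.7), group = "CORT/V"),
    make_scores(c("F1", "F2", "F3", "F4"), pre = c(2, 2, 2, 2),
                post = c(0.2, 0.4, 1.8, 1.8))
  )
  lab <- classify_response(sc)
  sel <- select_most_affected(sc, lab,
                              k_per_group = c("CORT/V" = 2,
                                              "CORT/Flx-R" = 2,
                                              "CORT/Flx-NR" = 2))
  cv <- sel[sel$proteome_group == "CORT/V", ]
  expect_equal(cv$animal_id, c("C1", "C3"))  # post 2.1 then 1.7

  # ties broken lexicographically by id: F3/F4 share post = 1.8
  nr <- sel[sel$proteome_group == "CORT/Flx-NR", ]
  expect_equal(nr$animal_id, c("F3", "F4"))

  # k = group size returns the whole group in rank order
  sel_all <- select_most_affected(sc, lab,
                                  k_per_group = c("CORT/V" = 3))
  expect_equal(sel_all$animal_id, c("C1", "C3", "C2"))
  expect_error(
    select_most_affected(sc, lab, k_per_group = c("CORT/V" = 4)),
    "exceeds")
})
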