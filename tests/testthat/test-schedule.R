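test_that("session spans follow the presentation geometry", {
  p <- engram_params()
  s <- training_session(1, 0, p)
  expect_equal(engramsim:::session_span(s, p), 20 * 40 + 19 * 150)  # 3650 ms
  pf <- engram_params("fear")
  sf <- training_session(1, 0, pf)
  expect_equal(engramsim:::session_span(sf, pf), 15 * 40 + 14 * 150) # 2700 ms
  r <- recall_session(1, 0, p)
  expect_equal(engramsim:::session_span(r, p), 40)
})

test_that("the phase plan tiles the timeline with the right resolutions", {
  p <- engram_params()
  sch <- experiment_schedule("two_context", p, delay_h = 6)
  plan <- phase_plan(sch, p)
  # contiguous: each phase starts where the previous one ends
  expect_equal(plan$start[-1], plan$end[-nrow(plan)])
  expect_equal(plan$start[1], 0)
  fine <- plan[plan$phase == "fine", ]
  expect_equal(fine$dt, rep(p$dt_fine, 4))
  expect_equal(plan$dt[plan$phase == "coarse"],
               rep(p$dt_coarse, sum(plan$phase == "coarse")))
  # training fine phases: session plus 3 s; recall: plus 300 ms
  expect_equal(fine$end[1] - fine$start[1], 3650 + 3000)
  expect_equal(fine$end[3] - fine$start[3], 40 + 300)
  # the fine step divides every presentation edge
  expect_true(all(c(p$stim_duration, p$isi, p$tag_delay) %% p$dt_fine == 0))
})

test_that("schedules are validated structurally", {
  p <- engram_params()
  s1 <- training_session(1, 0, p)
  s2 <- training_session(2, 1000, p)    # overlaps the first session
  expect_error(validate_schedule(dplyr::bind_rows(s1, s2), p), "overlap")

  bad <- recall_session(1, 0, p)
  bad$us <- TRUE
  expect_error(validate_schedule(bad, p), "unconditioned")

  bad2 <- recall_session(1, 0, p)
  bad2$n_presentations <- 3L
  expect_error(validate_schedule(bad2, p), "exactly one")

  expect_error(training_session(5, 0, p), "context")
})

test_that("named experiments lay out their protocols", {
  p <- engram_params()

  two <- experiment_schedule("two_context", p, delay_h = 6)
  expect_equal(two$start[2], 6 * 3600e3)                 # second training
  expect_equal(two$start[3], (6 + 24) * 3600e3)          # first recall
  expect_equal(two$start[4] - two$start[3], 25 * 60e3)   # 25 min apart
  expect_true(all(two$us[two$kind == "training"]))

  ov <- experiment_schedule("allocation_overlap", p, delay_h = 6)
  expect_true(ov$eps_plus[1])
  expect_true(ov$i_plus[ov$label == "recall_ctx2"])      # block at recall 2
  expect_false(any(ov$i_plus[ov$kind == "training"]))

  comp <- experiment_schedule("competition", p, delay_h = 6,
                              reduced_i1 = TRUE)
  expect_true(comp$i_plus[comp$label == "train_ctx2"])   # block during training
  expect_true(comp$reduced_i1[comp$label == "train_ctx2"])
  expect_false(any(comp$reduced_i1[comp$kind == "recall"]))

  pf <- engram_params("fear")
  fearS <- experiment_schedule("fear_linking", pf, shock = TRUE)
  fearN <- experiment_schedule("fear_linking", pf, shock = FALSE)
  expect_equal(sum(fearS$us), 1L)              # only the conditioning session
  expect_equal(nrow(fearS), nrow(fearN) + 1L)  # control omits it
  expect_equal(fearS$start[2], 7 * 24 * 3600e3)
  expect_equal(fearS$start[3] - fearS$start[2], 5 * 3600e3)

  tagrec <- experiment_schedule("two_context", p, variant = "tag_on_recall")
  expect_true(all(tagrec$tagging[tagrec$kind == "recall"]))

  expect_error(experiment_schedule("bogus", p))
})
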