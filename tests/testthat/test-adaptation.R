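test_that("events fire on persistence and map quadrants to their fixed actions", {
  p <- policy_step(c("HANV", "HANV"), persistence = 2)
  expect_equal(nrow(p$events), 1)
  expect_identical(p$events$action, "reward_bricks")
  expect_equal(p$events$step, 2)

  p2 <- policy_step("LANV", persistence = 1)
  expect_identical(p2$events$action, "new_scene")
  expect_equal(p2$n_new_scene, 1)
  expect_false(p2$session_end)

  expect_identical(policy_step("LAPV")$events$action, "spawn_monsters")
})

test_that("the ideal entertainment state is logged but never triggers an event", {
  p <- policy_step(rep("HAPV", 10))
  expect_equal(nrow(p$events), 0)
  expect_equal(sum(p$log$action == "no_action"), 10)
})

test_that("refractory windows suppress immediate re-triggering of the same quadrant", {
  p <- policy_step(rep("LANV", 6), persistence = 1, refractory = 1)
  expect_equal(p$events$step, c(1, 3, 5))
  # with no refractory and unit persistence, events copy the decision
  # stream minus HAPV and UNDECIDED
  dec <- c("HANV", "UNDECIDED", "LAPV", "HAPV", "LANV", "HANV")
  p0 <- policy_step(dec, persistence = 1, refractory = 0)
  expect_identical(p0$events$quadrant, c("HANV", "LAPV", "LANV", "HANV"))
})

test_that("UNDECIDED windows reset persistence and scene changes end the session", {
  p <- policy_step(c("HANV", "UNDECIDED", "HANV", "HANV"), persistence = 2)
  expect_equal(p$events$step, 4)  # the run before the reset never reaches 2
  p2 <- policy_step(c("LANV", "HANV", "LANV"), refractory = 0, session_end_after = 2)
  expect_true(p2$session_end)
})

test_that("activation tabulation produces per-subject rows and consistent subtotals", {
  mk <- function(q) data.frame(quadrant = q)
  streams <- list(
    `1` = mk(c("HANV", "HANV", "LAPV")),
    `2` = mk(c("LANV")),
    `3` = mk(character(0)),
    `4` = mk(c("LAPV", "LANV", "LANV"))
  )
  tab <- tabulate_activations(streams, participated_before = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tab$HANV[tab$subject == "total_1_2"], 2)
  expect_equal(tab$LANV[tab$subject == "total_1_4"], 3)
  expect_true(all(is.na(tab$HAPV)))
  # empty log yields an all-zero row
  expect_equal(unlist(tab[tab$subject == "3", c("HANV", "LAPV", "LANV")]),
               c(HANV = 0, LAPV = 0, LANV = 0))
  # subtotals equal the column sums of their member rows
  subj <- tab[tab$subject %in% as.character(1:4), ]
  expect_equal(tab$HANV[tab$subject == "total_1_4"], sum(subj$HANV))
  expect_error(tabulate_activations(setNames(streams, c("1", "1", "2", "3"))),
               class = "affectstream_invalid_argument")
})

test_that("event counts never exceed the decision counts that drive them", {
  s <- default_session()
  dec <- judge_session(default_prepped(), features = default_features())
  p <- policy_step(dec)
  for (q in c("HANV", "LAPV", "LANV")) {
    expect_lte(sum(p$events$quadrant == q), sum(dec$quadrant == q))
  }
})
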