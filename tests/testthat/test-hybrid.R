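.mkSelector <- function(seed = 71, n = 30) {
  fitSelector(rhoCloud(n, c(0.2, 0.2), seed = seed),
              rhoCloud(n, c(0.7, 0.3), seed = seed + 1),
              rhoCloud(n, c(0.3, 0.7), seed = seed + 2))
}

test_that("the arbiter separates synthetic correlation clouds", {
  sel <- .mkSelector()
  test <- rbind(rhoCloud(20, c(0.2, 0.2), seed = 81),
                rhoCloud(20, c(0.7, 0.3), seed = 82),
                rhoCloud(20, c(0.3, 0.7), seed = 83))
  truth <- rep(c("E", "S_l", "S_r"), each = 20)
  expect_gte(mean(predictRegion(sel, test) == truth), 0.9)
  # a point deep inside the left-stimulus cloud
  expect_equal(predictRegion(sel, c(0.75, 0.25)), "S_l")
  # every point of the unit square maps to exactly one region
  grid <- as.matrix(expand.grid(seq(0, 1, 0.1), seq(0, 1, 0.1)))
  expect_true(all(predictRegion(sel, grid) %in% c("E", "S_l", "S_r")))
})

test_that("swapping the stimulus clouds swaps the left/right decisions", {
  selA <- .mkSelector()
  selB <- fitSelector(rhoCloud(30, c(0.2, 0.2), seed = 71),
                      rhoCloud(30, c(0.3, 0.7), seed = 73),
                      rhoCloud(30, c(0.7, 0.3), seed = 72))
  pts <- rbind(c(0.7, 0.3), c(0.3, 0.7), c(0.65, 0.35))
  a <- predictRegion(selA, pts)
  b <- predictRegion(selB, pts)
  swap <- c(S_l = "S_r", S_r = "S_l")
  expect_equal(unname(swap[a]), b)
})

test_that("degenerate or underpopulated clouds are rejected", {
  same <- rhoCloud(15, c(0.5, 0.5), seed = 74)
  expect_error(fitSelector(same, same, same), "degenerate")
  expect_error(fitSelector(rhoCloud(5, c(0.2, 0.2)),
                           rhoCloud(15, c(0.7, 0.3)),
                           rhoCloud(15, c(0.3, 0.7))), "at least 10")
})

test_that("window classification routes regions to the right commands", {
  cfg <- SynthConfig(seed = 75, snr = 2)
  dec <- trainHybridDecoders(cfg)

  pure12 <- trialWindows(genSsvepTrials(SynthConfig(seed = 76, snr = 100),
                                        12, n = 1))[[1]]
  out <- classifyWindow(dec$selector, dec$csp, dec$classifier, pure12)
  expect_equal(out$command, "HEAD_LEFT")
  expect_equal(out$region, "S_l")

  nIdle <- 0; nActive <- 0; excl <- TRUE
  for (i in 1:25) {
    idleW <- trialWindows(genErdTrials(SynthConfig(seed = 800 + i, snr = 2),
                                       nActive = 0, nIdle = 1))[[1]]
    actW <- trialWindows(genErdTrials(SynthConfig(seed = 900 + i, snr = 2),
                                      nActive = 1, nIdle = 0,
                                      attenuation = 0.9))[[1]]
    oi <- classifyWindow(dec$selector, dec$csp, dec$classifier, idleW)
    oa <- classifyWindow(dec$selector, dec$csp, dec$classifier, actW)
    nIdle <- nIdle + (oi$command == "NONE")
    nActive <- nActive + (oa$command == "ERD_SWITCH")
    # region exclusivity: S regions only emit head turns, E only switch/none
    for (o in list(oi, oa)) {
      if (o$region == "E")
        excl <- excl && o$command %in% c("ERD_SWITCH", "NONE")
      else
        excl <- excl && o$command %in% c("HEAD_LEFT", "HEAD_RIGHT")
    }
  }
  expect_gte(nIdle / 25, 0.8)
  expect_gte(nActive / 25, 0.8)
  expect_true(excl)
})

test_that("the fading rule follows the printed hand traces", {
  run <- function(inputs) {
    st <- FadingState()
    confs <- character(0)
    for (x in inputs) {
      r <- fadingStep(st, x)
      st <- r$state
      if (!is.na(r$confirmed)) confs <- c(confs, r$confirmed)
    }
    list(state = st, confirmed = confs)
  }
  # five consistent inputs confirm on the fifth (1 s at 250 ms spacing)
  r5 <- run(rep("HEAD_LEFT", 5))
  expect_equal(r5$confirmed, "HEAD_LEFT")
  expect_true(is.na(r5$state@candidate))
  expect_equal(length(run(rep("HEAD_LEFT", 4))$confirmed), 0)

  # L,L then seven R: candidate decays, replaced, confirmed on the 9th
  r9 <- run(c("HEAD_LEFT", "HEAD_LEFT", rep("HEAD_RIGHT", 7)))
  expect_equal(r9$confirmed, "HEAD_RIGHT")
  r8 <- run(c("HEAD_LEFT", "HEAD_LEFT", rep("HEAD_RIGHT", 6)))
  expect_equal(length(r8$confirmed), 0)

  # alternation never confirms
  alt <- run(rep(c("HEAD_LEFT", "HEAD_RIGHT"), 20))
  expect_equal(length(alt$confirmed), 0)

  # NONE decrements, is never adopted, never confirmed
  rn <- run(rep("NONE", 10))
  expect_equal(length(rn$confirmed), 0)
  expect_true(is.na(rn$state@candidate))
  rd <- run(c("HEAD_LEFT", "HEAD_LEFT", "NONE", "NONE", "NONE"))
  expect_true(is.na(rd$state@candidate))  # decayed then emptied
})

test_that("fading state is pure, bounded, and needs five inputs minimum", {
  st <- FadingState("HEAD_LEFT", 2L)
  a <- fadingStep(st, "ERD_SWITCH")
  b <- fadingStep(st, "ERD_SWITCH")
  expect_identical(a, b)

  set.seed(77)
  cmds <- bciCommands()
  st <- FadingState()
  for (i in 1:300) {
    r <- fadingStep(st, sample(cmds, 1))
    st <- r$state
    expect_true(st@level >= 0L && st@level <= 4L)
  }

  # exhaustive: no input sequence of length <= 4 ever confirms
  for (len in 1:4) {
    grids <- do.call(expand.grid, rep(list(cmds), len))
    for (i in seq_len(nrow(grids))) {
      st <- FadingState()
      for (j in seq_len(len)) {
        r <- fadingStep(st, as.character(grids[i, j]))
        st <- r$state
        expect_true(is.na(r$confirmed))
      }
    }
  }
})
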