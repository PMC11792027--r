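test_that("exon skipping between A-B-C and A-C yields one ES event", {
  ann <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200), c(500, 600)))
  )
  ev <- enumerate_events(ann)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "ES")
  expect_equal(ev$event_id, "ES:chr1:+:200-500")
  expect_equal(ev$inclusion[[1]], "t1")
  expect_equal(ev$exclusion[[1]], "t2")
})

test_that("identical chains produce zero events", {
  ann <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400))),
    tx_fix("t2", "g1", "chr1", "+", list(c(90, 200), c(300, 450)))
  )
  expect_equal(nrow(enumerate_events(ann)), 0L)
})

test_that("intron retention: an intron of one chain inside an exon of another", {
  ann <- ann_fix(
    tx_fix("ret", "g1", "chr1", "+", list(c(100, 600))),
    tx_fix("spl", "g1", "chr1", "+", list(c(100, 200), c(300, 600)))
  )
  ev <- enumerate_events(ann)
  expect_equal(ev$type, "IR")
  expect_equal(ev$event_id, "IR:chr1:+:200-300")
  expect_equal(ev$inclusion[[1]], "ret")   # inclusion = intron retained
  expect_equal(ev$exclusion[[1]], "spl")
})

test_that("alternative donor/acceptor events are strand-aware and context-gated", {
  # shared acceptor 500, donors 200 vs 250 inside the same first exon
  plus_a5 <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(500, 600))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 250), c(500, 600)))
  )
  ev <- enumerate_events(plus_a5)
  expect_equal(ev$type, "ALT5")
  # inclusion = shorter intron = donor 250
  expect_equal(ev$inclusion[[1]], "t2")
  # the same geometry on the minus strand is an alternative 3' site
  minus_a3 <- ann_fix(
    tx_fix("t1", "g1", "chr1", "-", list(c(100, 200), c(500, 600))),
    tx_fix("t2", "g1", "chr1", "-", list(c(100, 250), c(500, 600)))
  )
  expect_equal(enumerate_events(minus_a3)$type, "ALT3")
  # shared donor, differing acceptors on plus strand -> ALT3
  plus_a3 <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(500, 600))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200), c(450, 600)))
  )
  ev3 <- enumerate_events(plus_a3)
  expect_equal(ev3$type, "ALT3")
  expect_equal(ev3$inclusion[[1]], "t2")
  # an exon-skipping pair must NOT emit companion ALT events
  es <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200), c(500, 600)))
  )
  expect_equal(enumerate_events(es)$type, "ES")
})

test_that("alternative first/last exons require a shared remaining chain", {
  af <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(500, 600), c(700, 800))),
    tx_fix("t2", "g1", "chr1", "+", list(c(300, 420), c(500, 600), c(700, 800)))
  )
  ev <- enumerate_events(af)
  expect_equal(ev$type, "AF")
  al <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(700, 800)))
  )
  ev2 <- enumerate_events(al)
  expect_equal(ev2$type, "AL")
  # same structures on the minus strand swap the labels
  af_minus <- ann_fix(
    tx_fix("t1", "g1", "chr1", "-", list(c(100, 200), c(500, 600), c(700, 800))),
    tx_fix("t2", "g1", "chr1", "-", list(c(300, 420), c(500, 600), c(700, 800)))
  )
  expect_equal(enumerate_events(af_minus)$type, "AL")
})

test_that("mutually exclusive internal exons between shared anchors", {
  ann <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(700, 800))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200), c(500, 600), c(700, 800)))
  )
  ev <- enumerate_events(ann)
  expect_true("MX" %in% ev$type)
  mx <- ev[ev$type == "MX", ]
  expect_equal(mx$inclusion[[1]], "t1")  # smaller exon start
  expect_equal(mx$exclusion[[1]], "t2")
})

test_that("enumeration is invariant to transcript order and relabeling", {
  ann1 <- ann_fix(
    tx_fix("a", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600))),
    tx_fix("b", "g1", "chr1", "+", list(c(100, 200), c(500, 600)))
  )
  ann2 <- ann_fix(
    tx_fix("zz", "g1", "chr1", "+", list(c(100, 200), c(500, 600))),
    tx_fix("aa", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600)))
  )
  e1 <- enumerate_events(ann1); e2 <- enumerate_events(ann2)
  expect_equal(e1$event_id, e2$event_id)
})

test_that("ES enumeration equals the exon-structure oracle on simulated annotations", {
  for (seed in c(61, 62)) {
    d <- withr::local_tempdir()
    sim <- simulate_dataset(sim_config(n_genes = 20, psi_n_genes = 5, seed = seed), d)
    ev <- enumerate_events(sim$truth$annotation)
    expect_setequal(ev$event_id[ev$type == "ES"], es_oracle(sim$truth$annotation))
  }
})

test_that("event testing: symmetry, PSI and the significance gate", {
  ann <- ann_fix(
    tx_fix("t1", "g1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600))),
    tx_fix("t2", "g1", "chr1", "+", list(c(100, 200), c(500, 600)))
  )
  ev <- enumerate_events(ann)
  mk <- function(a1, a2, b1, b2) {
    matrix(c(a1, a2, b1, b2), nrow = 2, byrow = TRUE,
           dimnames = list(c("t1", "t2"), c("A", "B")))
  }
  balanced <- test_events(ev, mk(50, 50, 50, 50), "A", "B")
  expect_equal(balanced$p_value, 1)
  expect_equal(balanced$delta_psi, 0)
  expect_false(balanced$significant)

  strong <- test_events(ev, mk(90, 10, 10, 90), "A", "B")
  expect_equal(strong$psi_a, 0.9)
  expect_equal(strong$psi_b, 0.1)
  expect_true(strong$significant)
  expect_equal(strong$p_value, fisher_oracle(90, 10, 10, 90), tolerance = 1e-9)

  # swapping conditions mirrors PSI and preserves p
  sw <- test_events(ev, mk(90, 10, 10, 90), "B", "A")
  expect_equal(sw$psi_a, strong$psi_b)
  expect_equal(sw$p_value, strong$p_value)

  # a p-value between 0.01 and 0.05 is not significant at the 0.01 gate
  mild <- test_events(ev, mk(35, 50, 65, 50), "A", "B")
  expect_gt(mild$p_value, 0.01)
  expect_lt(mild$p_value, 0.05)
  expect_false(mild$significant)

  # zero counts in one condition: untestable, PSI missing, p = 1
  zero <- test_events(ev, mk(0, 40, 0, 60), "A", "B")
  expect_false(zero$testable)
  expect_true(is.na(zero$psi_a))
  expect_equal(zero$p_value, 1)
})
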