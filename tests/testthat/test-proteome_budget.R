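test_that("translation efficiency is the copies/FPKM quotient with exclusions", {
  df <- toy_gene_df()
  te <- compute_translation_efficiency(df)
  expect_equal(te$s_i[te$id == "g1"], 20)
  expect_equal(attr(te, "excluded"), "g3")
  expect_equal(nrow(te), 4)
  # brute-force oracle on a large synthetic table
  sim <- simulate_budget_tables(n_genes = 1000, seed = 14)
  te2 <- compute_translation_efficiency(sim$table)
  oracle <- numeric(nrow(te2))
  for (i in seq_len(nrow(te2))) oracle[i] <- te2$copies_wt[i] / te2$r_wt[i]
  expect_identical(te2$s_i, oracle)
  expect_error(compute_translation_efficiency(toy_gene_df()[0, ]), "empty")
})

test_that("protein mass follows r*s*MW/N_A in femtograms", {
  # WT self-consistency hand case: 2000 copies of a 50 kDa protein
  expect_equal(estimate_protein_mass(100, 20, 50000), 0.16605, tolerance = 1e-4)
  expect_equal(round(estimate_protein_mass(100, 20, 50000), 4), 0.1661)
  # mutant case and its delta
  expect_equal(round(estimate_protein_mass(150, 20, 50000), 4), 0.2491)
  expect_equal(round(estimate_protein_mass(150, 20, 50000) -
                       estimate_protein_mass(100, 20, 50000), 4), 0.083)
  # dimensional sanity: 40 kDa at 1000 copies/cell
  expect_equal(round(estimate_protein_mass(1, 1000, 40000), 4), 0.0664)
  expect_equal(estimate_protein_mass(0, 20, 50000), 0)
  expect_error(estimate_protein_mass(-1, 1, 1), "non-negative")
})

test_that("WT self-consistency holds to machine precision on 1000 genes", {
  sim <- simulate_budget_tables(n_genes = 1000, seed = 23)
  te <- compute_translation_efficiency(sim$table)
  p_wt <- estimate_protein_mass(te$r_wt, te$s_i, te$mw)
  expect_equal(p_wt, te$copies_wt * te$mw / 6.02214076e23 * 1e15,
               tolerance = 1e-12)
})

test_that("deltas are linear in the transcript difference and conserve totals", {
  df <- toy_gene_df()
  te <- compute_translation_efficiency(df)
  mc1 <- mass_contribution_deltas(te)
  te2 <- te
  te2$r_mut <- te$r_wt + 2 * (te$r_mut - te$r_wt)
  mc2 <- mass_contribution_deltas(te2)
  d1 <- mc1$genes$delta[order(mc1$genes$id)]
  d2 <- mc2$genes$delta[order(mc2$genes$id)]
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # per-category totals sum to the grand total
  expect_equal(sum(mc1$by_category$signed), sum(mc1$genes$delta),
               tolerance = 1e-12)
  # identical mutant and WT transcripts mean zero change
  te0 <- te; te0$r_mut <- te0$r_wt
  mc0 <- mass_contribution_deltas(te0)
  expect_true(all(mc0$genes$delta == 0))
  expect_equal(mc0$up_total, 0)
})

test_that("planted direction totals and their ratio are reproduced exactly", {
  sim <- simulate_budget_tables(up_total_fg = 6.27, down_total_fg = 2.09,
                                seed = 9)
  mc <- mass_contribution_deltas(compute_translation_efficiency(sim$table))
  expect_equal(mc$up_total, 6.27, tolerance = 1e-9)
  expect_equal(mc$down_total, 2.09, tolerance = 1e-9)
  expect_equal(mc$ratio_up_down, 3.0, tolerance = 1e-9)
  # the simulator's own truth record agrees with the pipeline
  expect_equal(sum(abs(sim$truth$delta_fg[sim$truth$direction == "up"])),
               mc$up_total, tolerance = 1e-9)
})

test_that("Pareto ranking and cumulative percentages are correct", {
  genes <- data.frame(id = c("a", "b", "c", "d"),
                      r_wt = 1, r_mut = 1 + c(8, 1, 0.5, 0.5),
                      copies_wt = 1, mw = 6.02214076e23 / 1e15)
  te <- compute_translation_efficiency(genes)
  mc <- mass_contribution_deltas(te)
  ps <- pareto_summary(mc, top_n = 2)
  expect_equal(ps$table$cumulative_pct, c(80, 90, 95, 100))
  expect_equal(ps$table$id, c("a", "b", "c", "d"))  # ties broken by id
  expect_equal(ps$top_n_share_pct, 90)

  # single gene: 100% at rank 1
  mc1 <- mass_contribution_deltas(compute_translation_efficiency(genes[1, ]))
  expect_equal(pareto_summary(mc1)$table$cumulative_pct, 100)

  # property: cumulative curve is monotone and ends at 100 on random tables
  for (s in 1:5) {
    sim <- simulate_budget_tables(n_genes = 200, seed = s)
    cc <- pareto_summary(mass_contribution_deltas(
      compute_translation_efficiency(sim$table)))$table$cumulative_pct
    expect_true(all(diff(cc) >= -1e-9))
    expect_equal(cc[length(cc)], 100, tolerance = 1e-9)
  }
})

test_that("heavy-tailed contribution draws concentrate in the top 20", {
  # two-way computation of the top-20 share: pipeline vs direct loop
  sim <- simulate_budget_tables(n_genes = 100, frac_up = 0.5, frac_down = 0.5,
                                lfc_sd = 2, seed = 77)
  mc <- mass_contribution_deltas(compute_translation_efficiency(sim$table))
  ps <- pareto_summary(mc, top_n = 20)
  direct <- sort(abs(mc$genes$delta), decreasing = TRUE)
  expect_equal(ps$top_n_share_pct,
               100 * sum(direct[1:20]) / sum(direct), tolerance = 1e-9)
  expect_gt(ps$top_n_share_pct, 50)
})
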