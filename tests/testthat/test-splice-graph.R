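# Exon clusters, junction extraction and the nine-type event classifier.

test_that("extract_junctions deduplicates across transcripts", {
  ex <- make_gene(list(t1 = c(0, 100, 200, 300), t2 = c(0, 100, 200, 300, 400, 500)))
  j <- extract_junctions(ex)
  expect_equal(nrow(j), 2L)
  expect_true(jx_key("chrT", 100, 200, "+") %in% j$key)
  # single-exon transcript contributes nothing
  expect_equal(nrow(extract_junctions(make_gene(list(t1 = c(0, 100))))), 0L)
})

test_that("exon clusters use single-linkage overlap with half-open boundaries", {
  # overlap merges
  ex <- make_gene(list(t1 = c(0, 100), t2 = c(50, 150)))
  cl <- build_exon_clusters(ex)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(0L, 150L))
  # abutting exons stay distinct
  ex <- make_gene(list(t1 = c(0, 100), t2 = c(100, 200)))
  expect_equal(nrow(build_exon_clusters(ex)), 2L)
  # transitive closure: (0,100)+(50,150)+(140,200) -> one cluster (0,200);
  # brute-force check by pairwise-overlap closure
  ex <- make_gene(list(t1 = c(0, 100, 300, 400), t2 = c(50, 150), t3 = c(140, 200)))
  cl <- build_exon_clusters(ex)
  iv <- data.frame(s = c(0, 50, 140, 300), e = c(100, 150, 200, 400))
  adj <- outer(seq_len(4), seq_len(4), function(i, j) iv$s[i] < iv$e[j] & iv$s[j] < iv$e[i])
  reach <- adj
  for (k in 1:4) reach <- (reach %*% adj > 0) | reach
  n_comp <- length(unique(apply(reach, 1, function(r) min(which(r)))))
  expect_equal(nrow(cl), n_comp)
  expect_equal(cl$start, c(0L, 300L))
  expect_equal(cl$end, c(200L, 400L))
  # two strands in one gene is a validation error
  ex <- make_gene(list(t1 = c(0, 100)))
  ex2 <- make_gene(list(t2 = c(200, 300)), strand = "-")
  expect_error(build_exon_clusters(rbind(ex, ex2)), "strand")
})

test_that("strand_polarity maps junction sides to donor/acceptor", {
  expect_equal(strand_polarity("lower_coord", "+"), "donor")
  expect_equal(strand_polarity("lower_coord", "-"), "acceptor")
  expect_equal(strand_polarity("higher_coord", "+"), "acceptor")
  expect_equal(strand_polarity("higher_coord", "-"), "donor")
})

test_that("classifier recognizes each template with the documented junction sets", {
  # cassette: A-B-C vs A-C
  ex <- make_gene(list(t1 = c(0, 100, 200, 300, 400, 500), t2 = c(0, 100, 400, 500)))
  ev <- detect_events(ex)
  expect_equal(ev$event_type, "cassette")
  expect_equal(c(ev$start, ev$end), c(200L, 300L))
  expect_setequal(ev$inclusion_junctions[[1]],
                  jx_key("chrT", c(100, 300), c(200, 400), "+"))
  expect_equal(ev$exclusion_junctions[[1]], jx_key("chrT", 100, 400, "+"))

  # cassette_multi: A-B-C-D vs A-D
  ex <- make_gene(list(t1 = c(0, 100, 200, 300, 400, 500, 600, 700),
                       t2 = c(0, 100, 600, 700)))
  ev <- detect_events(ex)
  expect_equal(ev$event_type, "cassette_multi")
  expect_equal(c(ev$start, ev$end), c(200L, 500L))
  expect_length(ev$inclusion_junctions[[1]], 3L)

  # mutually exclusive: A-B-D vs A-C-D
  ex <- make_gene(list(t1 = c(0, 100, 200, 300, 600, 700),
                       t2 = c(0, 100, 400, 500, 600, 700)))
  ev <- detect_events(ex)
  expect_equal(ev$event_type, "mutually_exclusive")
  expect_equal(c(ev$start, ev$end), c(200L, 300L))
  expect_setequal(ev$inclusion_junctions[[1]],
                  jx_key("chrT", c(100, 300), c(200, 600), "+"))
  expect_setequal(ev$exclusion_junctions[[1]],
                  jx_key("chrT", c(100, 500), c(400, 600), "+"))

  # intron retention: exon spans the other isoform's intron entirely
  ex <- make_gene(list(t1 = c(0, 100, 200, 300), t2 = c(0, 300)))
  ev <- detect_events(ex)
  expect_equal(ev$event_type, "retain_intron")
  expect_equal(c(ev$start, ev$end), c(100L, 200L))
  expect_equal(ev$exclusion_junctions[[1]], jx_key("chrT", 100, 200, "+"))

  # unmatched structure falls through to unknown with a recorded reason
  ex <- make_gene(list(t1 = c(0, 100, 200, 300), t2 = c(0, 120, 180, 300)))
  ev <- detect_events(ex)
  expect_equal(ev$event_type, "unknown")
  expect_match(ev$reason, "no template")
  expect_true(length(ev$inclusion_junctions[[1]]) > 0)
})

test_that("alt-site labels are strand-aware (donor shift on + is alt5prime)", {
  ex <- make_gene(list(t1 = c(0, 100, 200, 300), t2 = c(0, 120, 200, 300)))
  ev <- detect_events(ex)
  expect_equal(ev$event_type, "alt5prime")
  expect_equal(c(ev$start, ev$end), c(100L, 120L))
  expect_equal(ev$inclusion_junctions[[1]], jx_key("chrT", 120, 200, "+"))
  expect_equal(ev$exclusion_junctions[[1]], jx_key("chrT", 100, 200, "+"))
  # same structure on the minus strand is an acceptor shift
  ex$strand <- "-"
  expect_equal(detect_events(ex)$event_type, "alt3prime")
})

test_that("terminal-exon variation is strand-aware (altstart at the 5' end)", {
  ex <- make_gene(list(t1 = c(0, 100, 500, 700), t2 = c(250, 350, 500, 700)))
  expect_equal(detect_events(ex)$event_type, "altstart")
  ex$strand <- "-"
  expect_equal(detect_events(ex)$event_type, "altend")
})

test_that("mirror+strand-flip preserves every label; flip alone swaps polar pairs", {
  cfg <- all_types_config(2L, seed = 5)
  ann <- generate_annotation(cfg)
  ev <- detect_events(ann$exons)
  mev <- detect_events(validate_exon_table(mirror_flip(ann$exons, M = 1e6)))
  expect_equal(sort(table(mev$event_type)), sort(table(ev$event_type)))
  # per-gene label equality under mirror+flip
  expect_equal(
    mev$event_type[order(mev$gene_id)],
    ev$event_type[order(ev$gene_id)]
  )
})

test_that("detect_events output is invariant to transcript input order", {
  cfg <- all_types_config(3L, seed = 2)
  ann <- generate_annotation(cfg)
  ev1 <- detect_events(ann$exons)
  set.seed(42)
  shuffled <- ann$exons[sample(nrow(ann$exons)), ]
  ev2 <- detect_events(shuffled)
  expect_equal(ev1$event_id, ev2$event_id)
  expect_equal(ev1$inclusion_junctions, ev2$inclusion_junctions)
  expect_equal(ev1$exclusion_junctions, ev2$exclusion_junctions)
})

test_that("single-transcript genes and identical isoforms yield no events", {
  ex <- make_gene(list(t1 = c(0, 100, 200, 300)))
  expect_equal(nrow(detect_events(ex)), 0L)
  ex <- make_gene(list(t1 = c(0, 100, 200, 300), t2 = c(0, 100, 200, 300)))
  expect_equal(nrow(detect_events(ex)), 0L)
})

test_that("inclusion and exclusion junction sets are always disjoint", {
  cfg <- all_types_config(3L, seed = 9)
  ev <- detect_events(generate_annotation(cfg)$exons)
  overlap <- mapply(function(a, b) length(intersect(a, b)),
                    ev$inclusion_junctions, ev$exclusion_junctions)
  expect_true(all(overlap == 0))
})
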