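test_that("shingling difference is the symmetric set difference", {
  expect_equal(shingling_difference(c("a", "b"), c("b", "c")), c("a", "c"))
  expect_equal(shingling_difference(c("a", "b"), c("a", "b")), character(0))
  expect_equal(shingling_difference(c("a"), c("b")), c("a", "b"))
  expect_equal(shingling_difference(character(0), c("x")), "x")
  # commutative
  expect_equal(shingling_difference(c("p", "q"), c("q", "r")),
               shingling_difference(c("q", "r"), c("p", "q")))
})

test_that("hashing is stable, 32-bit, and matches an independent FNV-1a", {
  frags <- c("C", "CC", "CCO", "c1ccccc1", "[NH4+]", "C[C@H](N)C(=O)O",
             "C(=C\\F)/F", "CC(=O)Oc1ccccc1C(=O)O")
  hs <- hash_shingling(frags)
  expect_true(all(hs$hashes >= 0 & hs$hashes < 2^32))
  expect_equal(hs$hashes, hs$hashes[order(hs$hashes)])
  expect_equal(names(hs$provenance), sprintf("%.0f", hs$hashes))
  for (f in frags) {
    h <- hash_shingling(f)$hashes
    expect_equal(h, r_fnv1a32(f), label = f)
  }
  # repeated call identical (determinism within and across sessions is the
  # contract; cross-process identity is exercised via the CLI)
  expect_identical(hash_shingling(frags), hs)
  # pigeonhole
  expect_lte(length(hs$hashes), length(frags))
  expect_equal(length(hash_shingling(character(0))$hashes), 0)
})

fake_hashed <- function(values, frags = as.character(values)) {
  o <- order(values)
  structure(list(hashes = as.numeric(values)[o],
                 provenance = setNames(as.list(frags[o]), sprintf("%.0f", values[o]))),
            class = "drfp_hashed")
}

test_that("folding sets residue-class bits and merges provenance", {
  fp <- fold_hashes(fake_hashed(5, "fragA"), 4)
  expect_equal(fp$bits, c(0L, 1L, 0L, 0L))       # 5 mod 4 = 1
  expect_equal(fp$bit_map, list("1" = "fragA"))

  fp0 <- fold_hashes(fake_hashed(numeric(0), character(0)), 8)
  expect_equal(fp0$bits, rep(0L, 8))
  expect_equal(length(fp0$bit_map), 0)

  fp2 <- fold_hashes(fake_hashed(c(3, 7), c("fragA", "fragB")), 4)
  expect_equal(sum(fp2$bits), 1)                 # 3 and 7 collide mod 4
  expect_equal(fp2$bit_map[["3"]], c("fragA", "fragB"))
  expect_equal(explain_bit(fp2, 3), c("fragA", "fragB"))
})

test_that("popcount obeys the folding algebra", {
  cfg <- drfp_config(radius = 3)
  rxs <- c("CCO.CC(=O)O>>CCOC(=O)C", "CCBr.CCN>>CCNCC.Br",
           "c1ccc(cc1)B(O)O.CCBr>>CCc1ccccc1.OB(O)O")
  for (rx in rxs) {
    rec <- parse_reaction(rx)
    sides <- merge_sides(rec)
    s <- shingling_difference(side_shingling(sides$left, cfg),
                              side_shingling(sides$right, cfg))
    hs <- hash_shingling(s)
    prev <- 0
    for (d in c(16, 32, 64, 128, 256, 512, 1024, 2048)) {
      pc <- sum(fold_hashes(hs, d)$bits)
      expect_lte(pc, length(s))
      expect_gte(pc, prev)  # d doubling preserves congruence classes
      prev <- pc
    }
  }
  # random hash sets obey the same law
  set.seed(42)
  for (i in 1:25) {
    hs <- fake_hashed(sample(0:(2^32 - 1), 60))
    prev <- 0
    for (d in c(16, 32, 64, 128, 256, 512, 1024, 2048)) {
      pc <- sum(fold_hashes(hs, d)$bits)
      expect_lte(pc, 60)
      expect_gte(pc, prev)
      prev <- pc
    }
  }
})

test_that("null reactions encode to the zero vector", {
  cfg <- drfp_config(n_bits = 512)
  expect_equal(sum(drfp_encode("CCO>>CCO", cfg)$bits), 0)
  # same molecule sets written differently on the two sides
  expect_equal(sum(drfp_encode("OCC.CC(=O)O>>CCO.OC(C)=O", cfg)$bits), 0)
  # multiplicity differences also cancel under set semantics
  expect_equal(sum(drfp_encode("CCO.CCO>>CCO", cfg)$bits), 0)
})

test_that("reverse reactions and reagent placement cannot be distinguished", {
  cfg <- drfp_config(n_bits = 1024)
  a <- drfp_encode("CCO.CC(=O)O>>CCOC(=O)C.O", cfg)
  b <- drfp_encode("CCOC(=O)C.O>>CCO.CC(=O)O", cfg)
  expect_identical(a$bits, b$bits)
  expect_identical(a$bit_map, b$bit_map)

  with_reagent <- drfp_encode("CCO>CC(=O)O>CCOC(=O)C.O", cfg)
  expect_identical(with_reagent$bits, a$bits)

  # molecule order within a side is irrelevant
  c1 <- drfp_encode("CC(=O)O.CCO>>CCOC(=O)C.O", cfg)
  expect_identical(c1$bits, a$bits)
})

test_that("input rendering of molecules does not change the fingerprint", {
  cfg <- drfp_config(n_bits = 256)
  a <- drfp_encode("CCO.CC(=O)O>>CCOC(=O)C", cfg)
  b <- drfp_encode("OCC.OC(C)=O>>O(CC)C(=O)C", cfg)
  expect_identical(a$bits, b$bits)
})

test_that("bit provenance explains exactly the set bits", {
  fp <- drfp_encode("CCO.CC(=O)O>[H+]>CCOC(=O)C", drfp_config(n_bits = 128))
  on_bits <- which(fp$bits == 1L) - 1L
  expect_equal(sort(as.integer(names(fp$bit_map))), sort(on_bits))
  expect_equal(sum(fp$bits), length(fp$bit_map))
  for (i in on_bits) expect_gt(length(explain_bit(fp, i)), 0)
  off <- setdiff(0:127, on_bits)[1]
  expect_equal(explain_bit(fp, off), character(0))
  expect_error(explain_bit(fp, -1), class = "drfp_index_error")
  expect_error(explain_bit(fp, 128), class = "drfp_index_error")
  # bit_map fragments come from the symmetric difference: ethanol-only
  # fragments that also occur in the ester must not appear
  all_frags <- unlist(fp$bit_map, use.names = FALSE)
  expect_false("CC" %in% all_frags)   # present on both sides, cancels
})

test_that("encode_many builds matrices, honouring strict and lenient modes", {
  cfg <- drfp_config(n_bits = 64)
  rxs <- c("CCO.CC(=O)O>>CCOC(=O)C", "CCBr.CCN>>CCNCC.Br")
  fps <- drfp_encode_many(rxs, cfg)
  expect_equal(dim(fps$bits), c(2L, 64L))
  expect_equal(fps$bits[1, ], drfp_encode(rxs[1], cfg)$bits)
  expect_equal(fps$bits[2, ], drfp_encode(rxs[2], cfg)$bits)

  empty <- drfp_encode_many(character(0), cfg)
  expect_equal(dim(empty$bits), c(0L, 64L))

  bad <- c(rxs[1], "broken>smiles", rxs[2])
  err <- tryCatch(drfp_encode_many(bad, cfg), condition = identity)
  expect_s3_class(err, "drfp_error")
  expect_match(conditionMessage(err), "reaction 2")

  expect_warning(fps2 <- drfp_encode_many(bad, cfg, lenient = TRUE), "failed")
  expect_equal(fps2$failed, 2L)
  expect_equal(sum(fps2$bits[2, ]), 0)
  expect_equal(fps2$bits[3, ], fps$bits[2, ])
})

test_that("encoding is reproducible within a session after cache clearing", {
  cfg <- drfp_config(n_bits = 2048)
  rx <- "c1ccc(cc1)B(O)O.CCBr>c1ccc(cc1)P(c1ccccc1)c1ccccc1>CCc1ccccc1.OB(O)O"
  a <- drfp_encode(rx, cfg)
  drfp_clear_cache()
  b <- drfp_encode(rx, cfg)
  expect_identical(a$bits, b$bits)
  expect_identical(a$bit_map, b$bit_map)
})
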