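test_that("parse_reaction splits the three fields and validates molecules", {
  rec <- parse_reaction("CCO.CC(=O)O>[H+]>CCOC(=O)C")
  expect_s3_class(rec, "reaction_record")
  expect_equal(rec$reactants, c("CCO", "CC(=O)O"))
  expect_equal(rec$reagents, "[H+]")
  expect_equal(rec$products, "CCOC(=O)C")
  expect_equal(rec$raw, "CCO.CC(=O)O>[H+]>CCOC(=O)C")

  rec2 <- parse_reaction("CCO>>CCO")
  expect_equal(rec2$reagents, character(0))
  expect_equal(rec2$reactants, "CCO")
  expect_equal(rec2$products, "CCO")
})

test_that("malformed and invalid reactions raise typed conditions", {
  expect_error(parse_reaction("CCO>CC"), class = "drfp_malformed_reaction")
  expect_error(parse_reaction("CCO>CC>O>N"), class = "drfp_malformed_reaction")
  expect_error(parse_reaction(">>CCO"), class = "drfp_empty_side")
  expect_error(parse_reaction("CCO>>"), class = "drfp_empty_side")
  expect_error(parse_reaction("CCQX>>CCO"), class = "drfp_unparsable_molecule")
  cond <- tryCatch(parse_reaction("CCO.CCQX>>CC"), condition = identity)
  expect_s3_class(cond, "drfp_unparsable_molecule")
  expect_equal(cond$component, "CCQX")
})

test_that("atom maps are stripped, giving the same canonical molecules", {
  mapped <- parse_reaction("[CH3:1][CH2:2][OH:3].[CH3:4][C:5](=[O:6])[OH:7]>>[CH3:4][C:5](=[O:6])[O:7][CH2:2][CH3:1]")
  plain <- parse_reaction("CCO.CC(=O)O>>CCOC(=O)C")
  canon <- function(rec) lapply(attr(rec, "canonical"), sort)
  expect_equal(canon(mapped), canon(plain))
})

test_that("parse_reaction is idempotent on its own re-rendering", {
  for (s in c("CCO.CC(=O)O>[H+]>CCOC(=O)C", "CCO>>CCO",
              "CCBr.CCN>CCN(CC)CC>CCNCC.Br")) {
    rec <- parse_reaction(s)
    rec2 <- parse_reaction(reaction_string(rec))
    expect_equal(rec2$reactants, rec$reactants)
    expect_equal(rec2$reagents, rec$reagents)
    expect_equal(rec2$products, rec$products)
  }
})

test_that("merge_sides appends reagents to reactants without deduplication", {
  rec <- parse_reaction("CCO>CC(=O)O>CCOC(=O)C")
  m <- merge_sides(rec)
  expect_equal(m$left, c("CCO", "CC(=O)O"))
  expect_equal(m$right, "CCOC(=O)C")

  rec2 <- parse_reaction("CCO.CCO.O>CCO>CCOCC")
  expect_equal(merge_sides(rec2)$left, c("CCO", "CCO", "O", "CCO"))

  rec3 <- parse_reaction("CCO>>CCOCC")
  expect_equal(merge_sides(rec3)$left, rec3$reactants)
})

test_that("read_reaction_table handles plain text, tables and both modes", {
  plain <- tempfile(fileext = ".smi")
  writeLines(c("CCO>>CCOCC", "CCBr.CCN>>CCNCC.Br", "CCO.CC(=O)O>>CCOC(=O)C"), plain)
  tab <- read_reaction_table(plain)
  expect_equal(length(tab$reactions), 3)
  expect_equal(tab$label_kind, "none")
  expect_equal(tab$reactions[2], "CCBr.CCN>>CCNCC.Br")

  csv <- tempfile(fileext = ".csv")
  writeLines(c("smiles,yield", "CCO>>CCOCC,81.5", "CCBr.CCN>>CCNCC.Br,12.0"), csv)
  tab2 <- read_reaction_table(csv, smiles_column = "smiles", label_column = "yield")
  expect_equal(tab2$label_kind, "yield")
  expect_equal(tab2$labels, c(81.5, 12.0))

  expect_error(read_reaction_table(csv, smiles_column = "nope"),
               class = "drfp_missing_column")

  bad <- tempfile(fileext = ".smi")
  writeLines(c("CCO>>CCOCC", "not-a-reaction", "CCO>>CCO"), bad)
  err <- tryCatch(read_reaction_table(bad), condition = identity)
  expect_s3_class(err, "drfp_error")
  expect_match(conditionMessage(err), "row 2")
  expect_warning(tab3 <- read_reaction_table(bad, lenient = TRUE), "row 2")
  expect_equal(length(tab3$reactions), 2)
  expect_equal(tab3$skipped, 2L)
})

test_that("fingerprint serialization round-trips in all three formats", {
  set.seed(7)
  m <- matrix(rbinom(10 * 2048, 1, 0.05), 10, 2048)
  storage.mode(m) <- "integer"
  for (fmt in c("dense", "sparse", "packed")) {
    path <- tempfile()
    write_fingerprints(m, path, format = fmt)
    back <- read_fingerprints(path, format = fmt)
    expect_identical(back, m, label = fmt)
  }
  # a matrix with an all-zero row survives the sparse format
  m0 <- rbind(m, 0L)
  path <- tempfile()
  write_fingerprints(m0, path, format = "sparse")
  expect_identical(read_fingerprints(path, "sparse"), m0)
})

test_that("sparse format matches its documented layout", {
  path <- tempfile()
  write_fingerprints(matrix(c(0L, 1L, 0L, 0L), 1, 4), path, format = "sparse")
  lines <- readLines(path)
  expect_equal(lines[2], "1")  # 0-based index of the single set bit
})

test_that("bit maps serialize to JSON, including the empty map", {
  path <- tempfile(fileext = ".json")
  write_bit_maps(list(), path)
  expect_equal(unclass(jsonlite::read_json(path)), list())
  fp <- drfp_encode("CCO.CC(=O)O>>CCOC(=O)C", drfp_config(n_bits = 64))
  write_bit_maps(fp$bit_map, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sort(names(back)), sort(names(fp$bit_map)))
})
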