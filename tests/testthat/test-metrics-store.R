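incl_schema <- c(time = "timestamp", sensor_id = "text", angle = "real")

new_incl_store <- function() {
  st <- metrics_store()
  define_endpoint(st, "inclination", incl_schema)
  st
}

test_that("endpoint definition is idempotent and schema-checked", {
  st <- metrics_store()
  expect_equal(define_endpoint(st, "inclination", incl_schema), "inclination")
  expect_silent(define_endpoint(st, "inclination", incl_schema))
  expect_error(define_endpoint(st, "inclination",
                               c(time = "timestamp", x = "real")),
               "different schema")
  expect_error(define_endpoint(st, "bare", c(x = "real")), "timestamp")
  expect_error(define_endpoint(st, "bad", c(x = "decimal", t = "timestamp")),
               "unknown column type")
})

test_that("insertion is typed and all-or-nothing", {
  st <- new_incl_store()
  recs <- list(list(time = 1, sensor_id = "thigh", angle = 0.1),
               list(time = 2, sensor_id = "shank", angle = 0.2),
               list(time = 3, sensor_id = "thigh", angle = 0.3))
  expect_equal(insert_records(st, "inclination", recs), 3L)
  expect_equal(insert_records(st, "inclination", list()), 0L)
  bad <- list(list(time = 4, sensor_id = "thigh", angle = 0.4),
              list(time = 5, sensor_id = 7, angle = 0.5))
  expect_error(insert_records(st, "inclination", bad), "record 2")
  expect_equal(nrow(query_records(st, "inclination")), 3L)  # batch rejected
  expect_error(insert_records(st, "nope", recs), "unknown endpoint")
})

test_that("query-string filters parse per the column-type rules", {
  f <- parse_filters("sensor_id=thigh", incl_schema)
  expect_equal(f[[1]], list(column = "sensor_id", op = "eq", value = "thigh"))
  f <- parse_filters("angle.gt=0.1&angle.lt=0.5", incl_schema)
  expect_equal(vapply(f, `[[`, "", "op"), c("gt", "lt"))
  expect_equal(vapply(f, `[[`, 0, "value"), c(0.1, 0.5))
  expect_error(parse_filters("sensor_id.gt=a", incl_schema),
               class = "gaitfusion_unsupported_operator")
  expect_error(parse_filters("height=3", incl_schema), "unknown column")
  expect_error(parse_filters("angle=1&angle=2", incl_schema), "duplicate")
  expect_error(parse_filters("angle.gt=x", incl_schema), "not numeric")
  expect_length(parse_filters("", incl_schema), 0L)
})

test_that("range queries use strict inequalities and insertion order", {
  st <- new_incl_store()
  insert_records(st, "inclination",
                 lapply(1:3, function(i)
                   list(time = i, sensor_id = "s", angle = i)))
  got <- query_records(st, "inclination", "angle.gt=1&angle.lt=3")
  expect_equal(got$angle, 2)
  expect_equal(nrow(query_records(st, "inclination", NULL)), 3L)
  expect_equal(nrow(query_records(st, "inclination", "sensor_id=nope")), 0L)
})

test_that("filtering agrees with a brute-force oracle on random instances", {
  set.seed(31)
  schema <- c(t = "timestamp", grp = "text", v = "real", k = "integer")
  for (rep in 1:15) {
    st <- metrics_store()
    define_endpoint(st, "m", schema)
    n <- sample(5:25, 1)
    recs <- lapply(seq_len(n), function(i)
      list(t = i, grp = sample(c("a", "b", "c"), 1),
           v = round(runif(1, 0, 1), 2), k = sample.int(5, 1)))
    insert_records(st, "m", recs)
    lo <- runif(1, 0, 0.5); hi <- runif(1, 0.5, 1)
    q <- sprintf("v.gt=%g&v.lt=%g&grp=%s", lo, hi, sample(c("a", "b"), 1))
    f <- parse_filters(q, schema)
    expect_equal(query_records(st, "m", f), brute_filter(query_records(st, "m"), f))
    # conjunction can only shrink the result
    expect_lte(nrow(query_records(st, "m", f)),
               min(nrow(query_records(st, "m", parse_filters(
                 sprintf("v.gt=%g", lo), schema)))))
  }
})

test_that("records round-trip through the JSON wire format and persistence", {
  st <- new_incl_store()
  recs <- list(list(time = 1.5, sensor_id = "thigh", angle = -0.25),
               list(time = 2.5, sensor_id = "shank", angle = 0.75))
  insert_records(st, "inclination", recs)
  json <- records_to_json(query_records(st, "inclination"))
  st2 <- new_incl_store()
  insert_records(st2, "inclination", records_from_json(json))
  expect_identical(query_records(st2, "inclination"),
                   query_records(st, "inclination"))
  p <- file.path(tempdir(), "store.json")
  save_store(st, p)
  st3 <- load_store(p)
  expect_identical(query_records(st3, "inclination"),
                   query_records(st, "inclination"))
})
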