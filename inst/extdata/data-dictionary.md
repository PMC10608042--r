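# Data dictionary: per-individual daily source CSVs

Layout written by `write_cohort()` and expected by `read_cohort()`:
one sub-directory per individual id containing the six source files below
plus `meta.json`; an optional top-level `truth.json` carries generator
ground truth for synthetic cohorts.  All dates are ISO-8601 (`YYYY-MM-DD`);
times are `HH:MM:SS` on a 24-hour local clock.

## behavior.csv — behavior log, three 8-hour shifts per day
| column | values |
|---|---|
| date | calendar day the behavior day starts on (07:00) |
| shift | `07-15`, `15-23`, `23-07` |
| status | `behavior`, `none`, `missing` (LOA/unrecorded), `time_sampled` |
| category | `AGG`, `SIB`, or empty; non-empty iff status is `behavior` |

## sleep.csv — nightly bed checks, keyed by the evening date
| column | values |
|---|---|
| date | evening date; the night runs into the following morning |
| hours | sleep duration in hours (raw; cleaning clamps to [0, 24]) |
| interruptions | count of sleep interruptions |
| menses | 0/1 flag (always 0 for male individuals) |

## bm.csv — bowel-movement log, one row per record
| column | values |
|---|---|
| date | calendar day |
| record_type | `event` (one BM), `no_bm` (explicit no-BM-today marker), `intervention` (laxative/medication/prune/fluid given) |
| reporter | `staff`, `nurse`, `hospital`, `self`, `parent` (parent rows are dropped during cleaning) |
| bristol | Bristol stool score 1–7, or empty |
| size | qualitative size text, or empty (used only to validate the event) |
| note | TRUE/FALSE: a staff note accompanies the record |

A day with neither an `event` nor a `no_bm` row counts as observed-with-no-BM
only until the 3-day buffer expires; afterwards its BM columns are missing.
The explicit `no_bm` marker is how a confirmed no-BM day is distinguished
from a merely unrecorded one — readers of external data must supply it.

## allergen.csv — pollen station counts (sparse; observed days only)
| column | values |
|---|---|
| date | observation date |
| tree, grass, weed | category counts (grains/m^3) |
| total | tree + grass + weed + unidentified (>= each category) |

## weather.csv — station core values with per-value quality flags
| column | values |
|---|---|
| date | calendar day |
| tmax, tmin | max/min temperature, degrees F |
| prcp, snow, snwd | precipitation, snowfall, snow depth, inches |
| qflag_tmax ... qflag_snwd | empty = clear; any non-empty string discards that value for that day |

## moon.csv — lunar ephemerides sampled at 07:00 local
| column | values |
|---|---|
| date | calendar day |
| rise, set, culmination | times; empty = did not occur that day (cleaning substitutes 00:00:00 / 23:59:59 for rise / set) |
| distance_km | earth-moon center distance |
| altitude_deg, azimuth_deg | moon position at 07:00 |
| shadow_m | shadow length of a 1 m object; empty = no shadow (becomes 0) |
| illum_pct | illuminated percentage of the disc, 0–100 |
| age_days | days since the last new moon (cleaning converts to % of the 29.530588-day cycle) |
| next_new, next_full | ISO datetimes of the next new/full moon (cleaning converts to whole-day differences) |

## meta.json
`id`, `sex` (`M`/`F`), `resident` (flag), `asd` (flag), `admission` date,
`age_at_start` (years), `loa_dates` (array of leave-of-absence dates).
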