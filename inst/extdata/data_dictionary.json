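{
  "missing_token": "",
  "columns": {
    "id": {"type": "string", "description": "opaque respondent identifier"},
    "age": {"type": "continuous", "unit": "years", "min": 18},
    "parity_primiparous": {"type": "binary", "description": "exactly one child (1) vs multiparous (0)"},
    "race_caucasian": {"type": "binary", "description": "Caucasian (1) vs other (0)"},
    "education_hs_or_more": {"type": "binary", "description": "high school or greater (1)"},
    "married": {"type": "binary", "description": "married (1)"},
    "diastasis_recti": {"type": "binary", "description": "diastasis recti diagnosis (1)"},
    "breastfeeding": {"type": "binary", "description": "breastfeeding or pumping (1)"},
    "incontinence_any": {"type": "binary", "description": "any incontinence: urine, feces and/or gas (1)"},
    "delivery": {"type": "categorical", "levels": ["vaginal", "cesarean", "other"], "description": "delivery type of youngest child; 'other' covers VBAC / assisted vaginal"},
    "fatigue_present": {"type": "binary", "description": "reports fatigue (1); respondents answering no are coded PAFS = 0"},
    "pafs_score": {"type": "integer", "unit": "points", "min": 0, "max": 30, "description": "Postpartum Accumulated Fatigue Scale total"},
    "epds_score": {"type": "integer", "unit": "points", "min": 0, "max": 30, "description": "Edinburgh Postnatal Depression Scale total"},
    "sleep_hours_avg": {"type": "continuous", "unit": "hours", "min": 0, "description": "average hours of sleep per night"},
    "sleep_interruptions": {"type": "ordinal", "levels": ["0", "1", "2", "3", "4", "5", ">5"], "description": "average sleep interruptions per night"},
    "weekly_mileage": {"type": "continuous", "unit": "miles", "min": 0},
    "weeks_to_first_run": {"type": "continuous", "unit": "weeks", "min": 0, "description": "time to first postpartum run"},
    "runner_type": {"type": "categorical", "levels": ["novice", "recreational", "elite"]},
    "stroller_running": {"type": "binary", "description": "currently running with a stroller (1)"},
    "previous_rri": {"type": "binary", "description": "previous running-related injury (1)"},
    "covid_mileage_change": {"type": "categorical", "levels": ["increased", "decreased", "no_change", "not_asked"], "description": "pandemic effect on mileage; 'not_asked' before the question was added"},
    "pain_with_running": {"type": "binary", "description": "outcome: current pain with running (1)"}
  }
}
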