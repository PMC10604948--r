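{
  "corrected": {
    "ANB":  {"class1": {"lo": 3.2,  "hi": 5.7},  "class2": {"op": "gt", "value": 5.7},  "class3": {"op": "lt", "value": 3.2}},
    "SNB":  {"class1": {"lo": 74.6, "hi": 78.7}, "class2": {"op": "lt", "value": 74.6}, "class3": {"op": "gt", "value": 78.7}},
    "SNA":  {"class1": {"lo": 79.4, "hi": 83.2}, "class2": {"op": "gt", "value": 83.2}, "class3": {"op": "lt", "value": 79.4}},
    "ODI":  {"class1": {"lo": 78.4, "hi": 80.5}, "class2": {"op": "gt", "value": 80.5}, "class3": {"op": "lt", "value": 78.4}},
    "APDI": {"class1": {"lo": 77.6, "hi": 85.2}, "class2": {"op": "lt", "value": 77.6}, "class3": {"op": "gt", "value": 85.2}},
    "FHI":  {"class1": {"lo": 0.65, "hi": 0.75}, "class2": {"op": "gt", "value": 0.75}, "class3": {"op": "lt", "value": 0.65}},
    "FMA":  {"class1": {"lo": 26.8, "hi": 31.4}, "class2": {"op": "gt", "value": 31.4}, "class3": {"op": "lt", "value": 26.8}}
  },
  "literal": {
    "ANB":  {"class1": {"lo": 3.2,  "hi": 5.7},  "class2": {"op": "gt", "value": 5.7},  "class3": {"op": "lt", "value": 3.5}},
    "SNB":  {"class1": {"lo": 74.6, "hi": 78.7}, "class2": {"op": "lt", "value": 74.6}, "class3": {"op": "lt", "value": 78.7}},
    "SNA":  {"class1": {"lo": 79.4, "hi": 83.2}, "class2": {"op": "gt", "value": 83.5}, "class3": {"op": "lt", "value": 79.4}},
    "ODI":  {"class1": {"lo": 78.4, "hi": 80.5}, "class2": {"op": "lt", "value": 80.5}, "class3": {"op": "lt", "value": 78.4}},
    "APDI": {"class1": {"lo": 77.6, "hi": 85.2}, "class2": {"op": "gt", "value": 77.6}, "class3": {"op": "gt", "value": 85.2}},
    "FHI":  {"class1": {"lo": 0.65, "hi": 0.75}, "class2": {"op": "gt", "value": 0.75}, "class3": {"op": "lt", "value": 0.65}},
    "FMA":  {"class1": {"lo": 26.8, "hi": 31.4}, "class2": {"op": "gt", "value": 31.4}, "class3": {"op": "lt", "value": 26.8}}
  }
}
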