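{
  "locale": "ja",
  "months": {
    "1月": 1,
    "2月": 2,
    "3月": 3,
    "4月": 4,
    "5月": 5,
    "6月": 6,
    "7月": 7,
    "8月": 8,
    "9月": 9,
    "10月": 10,
    "11月": 11,
    "12月": 12
  },
  "weekdays": {
    "月曜日": 1,
    "火曜日": 2,
    "水曜日": 3,
    "木曜日": 4,
    "金曜日": 5,
    "土曜日": 6,
    "日曜日": 7
  },
  "numbers": []
}
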