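rumor_id,date,emotion_tag
r00001,2020-01-20,neutral
r00002,2020-01-20,neutral
r00003,2020-01-20,neutral
r00004,2020-01-21,neutral
r00005,2020-01-21,neutral
r00006,2020-01-21,fear
r00007,2020-01-21,fear
r00008,2020-01-21,neutral
r00009,2020-01-21,neutral
r00010,2020-01-21,neutral
r00011,2020-01-22,neutral
r00012,2020-01-22,neutral
r00013,2020-01-22,neutral
r00014,2020-01-22,fear
r00015,2020-01-22,happiness
r00016,2020-01-23,fear
r00017,2020-01-23,neutral
r00018,2020-01-23,sadness
r00019,2020-01-23,neutral
r00020,2020-01-23,fear
r00021,2020-01-23,neutral
r00022,2020-01-24,fear
r00023,2020-01-24,neutral
r00024,2020-01-24,neutral
r00025,2020-01-24,fear
r00026,2020-01-24,anger
r00027,2020-01-24,neutral
r00028,2020-01-24,neutral
r00029,2020-01-24,neutral
r00030,2020-01-24,neutral
r00031,2020-01-24,neutral
r00032,2020-01-24,fear
r00033,2020-01-24,neutral
r00034,2020-01-24,fear
r00035,2020-01-25,fear
r00036,2020-01-25,neutral
r00037,2020-01-26,neutral
r00038,2020-01-26,anger
r00039,2020-01-26,neutral
r00040,2020-01-27,happiness
r00041,2020-01-27,neutral
r00042,2020-01-27,fear
r00043,2020-01-28,neutral
r00044,2020-01-28,neutral
r00045,2020-01-28,fear
r00046,2020-01-28,neutral
r00047,2020-01-28,neutral
r00048,2020-01-28,fear
r00049,2020-01-28,neutral
r00050,2020-01-28,fear
r00051,2020-01-29,neutral
r00052,2020-01-29,neutral
r00053,2020-01-29,fear
r00054,2020-01-29,neutral
r00055,2020-01-29,neutral
r00056,2020-01-29,anger
r00057,2020-01-29,neutral
r00058,2020-01-30,neutral
r00059,2020-01-30,happiness
r00060,2020-01-30,neutral
r00061,2020-01-30,neutral
r00062,2020-01-30,happiness
r00063,2020-01-30,fear
r00064,2020-01-30,neutral
r00065,2020-01-31,neutral
r00066,2020-01-31,neutral
r00067,2020-02-01,fear
r00068,2020-02-01,neutral
r00069,2020-02-01,anger
r00070,2020-02-01,neutral
r00071,2020-02-01,fear
r00072,2020-02-01,neutral
r00073,2020-02-01,neutral
r00074,2020-02-01,fear
r00075,2020-02-01,neutral
r00076,2020-02-01,fear
r00077,2020-02-01,neutral
r00078,2020-02-02,neutral
r00079,2020-02-02,fear
r00080,2020-02-03,fear
r00081,2020-02-03,fear
r00082,2020-02-03,neutral
r00083,2020-02-03,fear
r00084,2020-02-03,neutral
r00085,2020-02-03,neutral
r00086,2020-02-04,fear
r00087,2020-02-04,anger
r00088,2020-02-05,neutral
r00089,2020-02-05,neutral
r00090,2020-02-06,happiness
r00091,2020-02-06,neutral
r00092,2020-02-06,neutral
r00093,2020-02-06,neutral
r00094,2020-02-06,fear
r00095,2020-02-06,fear
r00096,2020-02-06,fear
r00097,2020-02-06,neutral
r00098,2020-02-07,happiness
r00099,2020-02-07,neutral
r00100,2020-02-07,neutral
r00101,2020-02-07,neutral
r00102,2020-02-07,sadness
r00103,2020-02-07,neutral
r00104,2020-02-07,happiness
r00105,2020-02-07,neutral
r00106,2020-02-07,neutral
r00107,2020-02-07,happiness
r00108,2020-02-07,fear
r00109,2020-02-08,fear
r00110,2020-02-08,fear
r00111,2020-02-08,fear
r00112,2020-02-08,neutral
r00113,2020-02-08,fear
r00114,2020-02-08,neutral
r00115,2020-02-08,neutral
r00116,2020-02-09,fear
r00117,2020-02-09,fear
r00118,2020-02-09,neutral
r00119,2020-02-10,neutral
r00120,2020-02-10,anger
r00121,2020-02-10,anger
r00122,2020-02-10,fear
r00123,2020-02-10,fear
r00124,2020-02-10,anger
r00125,2020-02-10,sadness
r00126,2020-02-10,neutral
r00127,2020-02-11,neutral
r00128,2020-02-12,neutral
r00129,2020-02-12,fear
r00130,2020-02-12,fear
r00131,2020-02-13,neutral
r00132,2020-02-13,neutral
r00133,2020-02-15,neutral
r00134,2020-02-15,neutral
r00135,2020-02-15,neutral
r00136,2020-02-16,neutral
r00137,2020-02-16,neutral
r00138,2020-02-16,sadness
r00139,2020-02-16,neutral
r00140,2020-02-16,neutral
r00141,2020-02-16,fear
r00142,2020-02-17,happiness
r00143,2020-02-17,fear
r00144,2020-02-17,fear
r00145,2020-02-18,anger
r00146,2020-02-18,neutral
r00147,2020-02-18,fear
r00148,2020-02-18,neutral
r00149,2020-02-18,neutral
r00150,2020-02-18,neutral
r00151,2020-02-18,fear
r00152,2020-02-18,neutral
r00153,2020-02-18,happiness
r00154,2020-02-18,fear
r00155,2020-02-18,neutral
r00156,2020-02-18,neutral
r00157,2020-02-18,neutral
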