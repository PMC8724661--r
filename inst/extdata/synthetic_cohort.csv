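subject_id,time,response,bmi,lvl,art,age
S001,0,26.6794793550699,27.2000978968087,0,0,22
S001,1,29.0383936920118,27.2000978968087,0,0,22
S001,2,30.0575192311279,27.2000978968087,0,0,22
S001,3,25.5944985465407,27.2000978968087,0,1,22
S001,4,28.0985417623347,27.2000978968087,0,1,22
S001,5,30.0561975300665,27.2000978968087,0,1,22
S001,6,27.1316389369174,27.2000978968087,0,1,22
S001,7,27.2191810528618,27.2000978968087,0,1,22
S001,8,30.7336587128458,27.2000978968087,0,1,22
S002,0,18.805761605708,35.815948115701,14.1372215338951,0,30
S002,1,19.2759703285274,35.815948115701,14.1372215338951,1,30
S002,2,21.0835032965154,35.815948115701,14.1372215338951,1,30
S002,3,16.1788924842619,35.815948115701,14.1372215338951,1,30
S002,4,20.7728211032519,35.815948115701,14.1372215338951,1,30
S002,5,19.9677633760064,35.815948115701,14.1372215338951,1,30
S002,6,17.1084612766223,35.815948115701,14.1372215338951,1,30
S003,0,23.0731091260539,27.9728761930064,0,0,29
S003,1,25.8916959156615,27.9728761930064,0,0,29
S003,2,29.9881469778074,27.9728761930064,0,1,29
S003,3,29.4343820727382,27.9728761930064,0,1,29
S003,4,30.0498860401454,27.9728761930064,0,1,29
S003,5,25.7668814701378,27.9728761930064,0,1,29
S003,6,32.2295477777885,27.9728761930064,0,1,29
S003,7,26.6760222953667,27.9728761930064,0,1,29
S004,0,17.1060299772953,33.9787597022119,13.7494938176717,0,20
S004,1,22.7101580860542,33.9787597022119,13.7494938176717,1,20
S004,2,20.5359646008237,33.9787597022119,13.7494938176717,1,20
S004,3,22.9449994529842,33.9787597022119,13.7494938176717,1,20
S004,4,20.7825552901037,33.9787597022119,13.7494938176717,1,20
S005,0,20.8866531782726,32.1174974446404,12.7519537729359,0,27
S005,1,23.1868172187208,32.1174974446404,12.7519537729359,1,27
S005,2,19.1598410412166,32.1174974446404,12.7519537729359,1,27
S005,3,15.0487789577377,32.1174974446404,12.7519537729359,1,27
S006,0,17.1902009855316,33.4539210529571,10.990679832742,0,29
S006,1,20.471503924228,33.4539210529571,10.990679832742,0,29
S006,2,26.1213624847904,33.4539210529571,10.990679832742,1,29
S006,3,22.1889399432369,33.4539210529571,10.990679832742,1,29
S006,4,22.3717959291289,33.4539210529571,10.990679832742,1,29
S006,5,20.0014436921483,33.4539210529571,10.990679832742,1,29
S006,6,21.9631002553588,33.4539210529571,10.990679832742,1,29
S007,0,16.1533574418818,27.1711743542538,14.0654975048728,0,31
S007,1,17.6036497838176,27.1711743542538,14.0654975048728,0,31
S007,2,16.9726190219062,27.1711743542538,14.0654975048728,0,31
S007,3,15.1202275475208,27.1711743542538,14.0654975048728,0,31
S007,4,16.2584956901809,27.1711743542538,14.0654975048728,0,31
S007,5,19.6871192984455,27.1711743542538,14.0654975048728,0,31
S007,6,20.8688767581232,27.1711743542538,14.0654975048728,1,31
S007,7,21.1332098520553,27.1711743542538,14.0654975048728,1,31
S007,8,21.6948653346759,27.1711743542538,14.0654975048728,1,31
S007,9,21.7356181371899,27.1711743542538,14.0654975048728,1,31
S008,0,17.3032676556876,31.2838427327213,10.8742477797256,1,22
S008,1,21.5948502518236,31.2838427327213,10.8742477797256,1,22
S008,2,19.8466486169956,31.2838427327213,10.8742477797256,1,22
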