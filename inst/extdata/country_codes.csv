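alpha2,alpha3,name
AF,AFG,Afghanistan
AR,ARG,Argentina
AT,AUT,Austria
AU,AUS,Australia
BD,BGD,Bangladesh
BE,BEL,Belgium
BG,BGR,Bulgaria
BO,BOL,Bolivia
BR,BRA,Brazil
CA,CAN,Canada
CH,CHE,Switzerland
CI,CIV,Cote d'Ivoire
CL,CHL,Chile
CN,CHN,China
CO,COL,Colombia
CZ,CZE,Czechia
DE,DEU,Germany
DK,DNK,Denmark
EC,ECU,Ecuador
EG,EGY,Egypt
ES,ESP,Spain
ET,ETH,Ethiopia
FI,FIN,Finland
FR,FRA,France
GB,GBR,United Kingdom
GH,GHA,Ghana
GR,GRC,Greece
HU,HUN,Hungary
ID,IDN,Indonesia
IL,ISR,Israel
IN,IND,India
IR,IRN,Iran
IS,ISL,Iceland
IT,ITA,Italy
JP,JPN,Japan
KE,KEN,Kenya
KR,KOR,South Korea
KZ,KAZ,Kazakhstan
LB,LBN,Lebanon
LK,LKA,Sri Lanka
MA,MAR,Morocco
MM,MMR,Myanmar
MX,MEX,Mexico
MY,MYS,Malaysia
NE,NER,Niger
NG,NGA,Nigeria
NL,NLD,Netherlands
NO,NOR,Norway
NP,NPL,Nepal
PE,PER,Peru
PG,PNG,Papua New Guinea
PH,PHL,Philippines
PK,PAK,Pakistan
PL,POL,Poland
PT,PRT,Portugal
RO,ROU,Romania
RS,SRB,Serbia
RU,RUS,Russia
SE,SWE,Sweden
SK,SVK,Slovakia
SY,SYR,Syria
TH,THA,Thailand
TR,TUR,Turkey
TW,TWN,Taiwan
TZ,TZA,Tanzania
UA,UKR,Ukraine
UG,UGA,Uganda
US,USA,United States
UZ,UZB,Uzbekistan
VN,VNM,Vietnam
ZA,ZAF,South Africa
ZM,ZMB,Zambia
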