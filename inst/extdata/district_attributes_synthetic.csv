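location_name,temperature_c,humidity_pct,wind_kmh,precip_mm_day,uv_index,soil_moisture_vwc,terrain
"Udaipur, Rajasthan",33,30,12,2,7,0.12,plain
"Raipur, Chattisgarh",29,62,8,6,5,0.24,plain
"Palampur, HP",22,55,10,4,4,0.22,hilly
"Anand, Gujarat",31,38,14,3,7,0.15,plain
"Jabalpur, MP",27,58,9,7,5,0.26,plain
"Faizabad, UP",26,52,7,5,5,0.21,plain
"Parbhani, Maharashtra",34,32,15,2,8,0.11,plain
"Anantapur, AP",35,28,13,1,9,0.09,plain
"Bangalore, Karnataka",33,36,11,3,8,0.14,plain
"Jammu, J&K",24,50,9,6,4,0.23,hilly
"Hisar, Haryana",32,34,16,2,7,0.12,plain
"Ranchi, Jharkhand",25,75,8,14,5,0.38,hilly
"Ludhiana, Punjab",28,48,10,4,6,0.20,plain
"Thrissur, Kerala",29,85,12,22,6,0.45,plain
"Jorhat, Assam",26,88,7,25,4,0.48,plain
"Kanpur, UP",27,60,9,6,5,0.25,plain
"Dapoli, Maharashtra",28,82,14,20,6,0.42,hilly
"Bhubaneswar, Orissa",31,78,13,16,7,0.40,plain
"Mohanpur, UP",26,56,8,5,5,0.22,plain
"Kovilpatti, TN",33,72,15,12,9,0.34,plain
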